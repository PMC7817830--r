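---
title: "Identifying and quantifying SUMO-conjugated peptides: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying and quantifying SUMO-conjugated peptides: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(branchms)
```

## The branched-peptide model

SUMOylation attaches a SUMO protein to a substrate lysine through an
isopeptide bond. After tryptic digestion the substrate peptide retains a
C-terminal stub of SUMO — the *remnant* — on that lysine. For human SUMO1
the tryptic remnant is the 19-mer `ELGMEEEDVIEVYQEQTGG`; a harsher
digestion convention leaves only `QTGG`. Both are supported as the branch
of a `branched_conjugate()`; we make no attempt to decide which a given
experiment produces, because the arithmetic is identical and the choice
is a constructor argument.

The conjugate is a *branched* peptide: a tryptic backbone with the
remnant isopeptide-linked at one lysine. Forming the bond releases one
water, which exactly cancels the remnant's terminal water, so

> conjugate neutral mass = backbone peptide mass + branch residue-sum mass.

All masses are monoisotopic and derived from elemental compositions of
the 20 residues, with one deliberate exception: protein-level molecular
weights (`peptide_mass(kind = "average")`) use average masses, because
that is the scale a gel-band "kDa" statement refers to.

### Fragment series and the y′ convention

Collision-induced fragmentation cleaves amide bonds on either arm, so a
branched conjugate emits four series:

* **backbone-b / backbone-y** — ordinary b/y ions of the backbone; any
  fragment spanning the link position carries the *intact* branch.
* **branch-b** — N-terminal remnant fragments. These contain no backbone
  at all, which is what makes them usable as substrate-independent
  diagnostics.
* **branch-y′** — C-terminal remnant fragments, which necessarily retain
  the entire backbone (with its water) through the isopeptide link.

The y′ notation is not standardized in the field; we define y′n as the
remnant's n C-terminal residues plus the intact backbone. This
interpretation is pinned by the package's tests: it reproduces the eight
printed reference transitions of the K270 conjugate of pyruvate kinase
M2 (PKM2) — native y′2/y′3/y′5 at 2+ and b4 at 3+, and their
heavy-standard counterparts — to within ±0.01 m/z after half-up rounding
to two decimals, and no alternative assignment we tried does. One value
(native y′2) computes to 754.91 against a conventionally quoted 754.92;
the heavy partner and the heavy−light spacing (6.0138 Da / 2) are exact,
which suggests the quoted native value was derived from the heavy one by
subtracting a rounded 3.00.

Complementarity identities hold by construction and are tested as
properties: `neutral(branch-y′n) + neutral(branch-b(B−n))` equals the
conjugate mass for every n, and the analogous b/y identity holds for
linear peptides.

### Isotope labels

Heavy standards carry uniform ^13^C/^15^N residues. `isotope_shift()`
computes the increment from the residue's elemental composition
(Leu +7.01716 Da, Val +6.01381 Da), and label shifts follow their
residues into every fragment that contains them — so a branch-y′ ion
inherits backbone labels, and a backbone-b ion spanning the link inherits
branch labels. The label-additivity property (fragment m/z difference =
contained shifts / charge) is tested over random labeled conjugates.

## Digestion and conjugate enumeration

Trypsin cleaves C-terminal to K or R except before proline. A conjugated
lysine blocks cleavage at that residue, so a conjugate backbone always
carries at least one missed cleavage: for PKM2's K270 the backbone is the
1-missed-cleavage peptide `IISKIENHEGVR`, never `IISK`. Enumeration
therefore pairs every digest peptide with its *internal* lysines (plus a
protein C-terminal lysine), skipping peptide C-terminal lysines that
trypsin would have had to cut. A K→R substitution removes the site and
provably yields no conjugate there — the in silico analogue of the
site-mutation control.

## The three-stage DIA identification

The acquisition model is a cycled SWATH scheme: each cycle records one
MS1 spectrum and one MS2 spectrum per isolation window, with the
quadrupole stepped in 25-amu increments over m/z 600–1250 (26 windows,
half-open `[low, high)` so boundary peaks are never double-counted).

1. **Diagnostic-ion screening.** The remnant's branch-b ions are free of
   backbone content, so their co-elution in a window flags *some*
   conjugated peptide without knowing the substrate. The default panel
   for the SUMO1 19-mer is the singly charged b1..b18 plus the doubly
   charged b18 — 19 ions; for other remnants the default is the singly
   charged b-series, and any explicit ion list can be configured. Per
   window, each diagnostic's extracted ion chromatogram (XIC) is scanned
   for local apexes; a candidate is reported where at least *k* (default
   5) diagnostics apex within one cycle period of a common time.
2. **Precursor matching.** At the candidate (window, time), MS1 peaks
   inside the window are deconvoluted by trying each charge in a
   configured range (default 2–5); a peak at m/z with charge z implies a
   neutral mass z·(m/z − proton). Isotope-envelope deconvolution is
   deliberately out of scope — charge trial against the database is the
   minimal mechanism the matching step needs. Hypotheses within the MS1
   tolerance are ranked by |ppm|; "no MS1 peak in the window" is flagged
   distinctly from "peaks present but nothing matched".
3. **Fragment mapping.** The hypothesis conjugate's theoretical fragments
   (all four series, charges 1–2 by default) are matched against the
   window's MS2 spectrum; the score is the matched fraction of
   theoretical ions plus an intensity-weighted variant, and the localized
   site is the conjugate's link position, reported as
   `K<site> conjugated with <remnant> remnant`. The acceptance floor
   (default 0.3 matched fraction) is a filter, not a truth claim: records
   always carry their raw scores.

Defaults of 15 ppm (MS1) and 25 ppm (MS2) are typical for a high-
resolution QTOF; every threshold is exposed in `dia_settings()` and the
single YAML configuration. Raising *k* or the score floor can only shrink
the record list (tested as a monotonicity property).

## MRM transition design and quantification

`design_transitions()` ranks candidate products by a reference MS/MS
spectrum when one is available; otherwise it falls back to a
deterministic proxy (inverse emission-order rank — the same convention
the simulator's intensity model uses, chosen so design is exercisable
without claiming spectral realism). An explicit product list bypasses
ranking, which is how the canonical four-transition assay
(y′2/y′3/y′5 at 2+, b4 at 3+) is expressed. Each selected product is
emitted as a light/heavy pair; the heavy m/z is recomputed from the
labeled conjugate, never obtained by adding a constant.

Peak integration uses the simplest defensible scheme, with every constant
configurable: apex nearest the retention-time hint (global maximum
without one), boundaries walked outward to the first sample at or below
5% of apex height or to a local minimum, trapezoidal area, and a flat
baseline at the lower boundary intensity. Two numerical consequences are
worth stating plainly:

* The 5% cut plus baseline subtraction *truncates* an isolated Gaussian
  peak to about 89% of its closed-form area A·σ·√(2π). The unit tests
  assert agreement with the analytically truncated value at the default,
  and with the full closed form at `boundary_frac = 0.005`.
* Light and heavy traces of a transition pair share the peak shape, so
  the truncation bias cancels in the light/heavy *ratio* — which is the
  quantity the assay reports. Ratio recovery, not absolute area, is the
  acceptance-grade property.

Transitions of one peptide co-integrate at a consensus apex (median of
per-trace apexes; deviants beyond `apex_tol_s` are flagged and integrated
at the consensus). A zero heavy sum flags the ratio undefined rather than
returning infinity.

## What the simulator emulates — and what it does not

`simulate_dia()` reproduces the acquisition *structure*: cycled MS1 +
windowed MS2 spectra, a planted conjugate eluting as a Gaussian in time
(apex 40 s, σ 5 s over an 80 s run at a 2 s cycle period), its full
theoretical fragment set in the correct window with 1/rank relative
intensities, uniform-m/z noise peaks with log-uniform intensities
(50 per spectrum, ceiling at half the planted apex), and 5 ppm uniform
m/z jitter on planted peaks. `simulate_mrm()` plants Gaussian peaks whose
areas realize a requested light/heavy ratio on a small uniform baseline
(ceiling 0.2% of the tallest heavy apex — high-S/N targeted acquisition).
Identical seeds give byte-identical output, and the generators restore
the caller's RNG state.

Deliberately **not** modeled: isotope envelopes, chimeric
co-fragmentation, ion mobility, retention-time drift between runs,
intensity-dependent detector noise, and interference between windows.
Passing the recovery tests therefore demonstrates that the pipeline's
logic is correct and its thresholds self-consistent under the stated
noise model — not that real instrument data of arbitrary quality would
yield the same sensitivity. The synthetic substrate
(`fixture_proteins()`) embeds the K270 backbone between clean tryptic
boundaries precisely so ground truth is unambiguous; full-protein runs
accept any user FASTA.

Problem sizes used by the test suite — 40-cycle runs, 26 windows, 20
seeded replicates for recovery and null calibration, 20 MRM runs across
ratios 0.1–10 — were chosen as the smallest sizes at which the binomial
recovery criterion (≥95% of replicates) and the median-ratio-error
criterion (≤5%) are meaningful.

## Known limitations

* No false-discovery-rate machinery (target-decoy) — the specificity
  argument rests on the diagnostic co-elution requirement and the null
  simulations.
* Only b/y-type series; no neutral losses or internal fragments, no
  non-tryptic proteases.
* The 19-ion diagnostic panel's historical composition is not
  recoverable from any printed source we know; the default here is a
  defensible reconstruction (backbone-free ions, count pinned at 19) and
  is fully configurable.
* mzML reading requires the mzR package; the JSON-lines dialect is the
  native, dependency-free interchange format.
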