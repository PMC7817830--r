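# branchms

Mapping and quantifying SUMO conjugation sites by mass spectrometry, for
proteomics analysts working with branched (isopeptide-linked) peptides.
The motivating application is the SUMO1 conjugation of pyruvate kinase M2
(PKM2) at K270, but every component is generic over substrate, remnant
and site.

After tryptic digestion, a SUMOylated lysine retains a remnant peptide
(for SUMO1 the 19-mer ELGMEEEDVIEVYQEQTGG, or the short form QTGG) bound
through an isopeptide bond. The resulting *branched* peptide — backbone
`IISKIENHEGVR` carrying the remnant at K4, written
`ELGMEEEDVIEVYQEQTGG(IIS)K IENHEGVR` — has its own fragment-ion algebra:

* **backbone b/y ions**, which carry the intact branch whenever they span
  the link position;
* **branch b ions** (`b1..b18` for the 19-mer), free of the backbone and
  therefore usable as substrate-independent *diagnostic ions*;
* **branch y′ ions**, defined here as the remnant's y-type fragments
  retaining the entire intact backbone through the link: `y′n` has
  neutral mass `Σ(last n remnant residues) + M(backbone)`.

On this arithmetic the package builds the two workflows of a
SUMO-site-mapping study:

1. **DIA/SWATH identification** in three stages — per-window screening of
   the 19 remnant diagnostic ions across extracted ion chromatograms,
   charge-trial deconvolution of window precursors against an in silico
   conjugate database, and MS/MS fragment mapping with site localization
   (`K270 conjugated with … remnant`).
2. **MRM quantification** — light/heavy transition design (the canonical
   assay monitors y′2, y′3, y′5 at 2+ and b4 at 3+, with a
   ¹³C/¹⁵N-labeled heavy standard) and chromatographic peak-area
   integration to a light/heavy ratio.

A seeded simulator generates DIA runs and MRM chromatograms with planted
signals and a ground-truth manifest, so the whole pipeline is testable
without instrument data.

## Worked example

Build the K270 conjugate, design the four-transition assay with its
heavy standard, and quantify a simulated run:

```r
library(branchms)

bc <- branched_conjugate("IISKIENHEGVR", 4, protein_site = 270)
#> <branched_conjugate> IISK(+ELGMEEEDVIEVYQEQTGG)IENHEGVR
#>   link K at backbone position 4 (protein site K270)
#>   neutral monoisotopic mass 3529.6883 Da

labels <- make_heavy_labels(bc, backbone_positions = 11, branch_positions = 2)
tr <- design_transitions(bc,
  products = data.frame(series = c("branch-y'", "branch-y'", "branch-y'", "backbone-b"),
                        index = c(2, 3, 5, 4), charge = c(2, 2, 2, 3)),
  heavy_labels = labels, peptide_id = "PKM2_K270")
#>   product isotope precursor_mz product_mz
#> 1  y'2^2+   light      1177.57     754.91
#> 2  y'3^2+   light      1177.57     805.44
#> 3  y'5^2+   light      1177.57     933.99
#> 4   b4^3+   light      1177.57     860.08
#> 5  y'2^2+   heavy      1181.91     757.92
#> 6  y'3^2+   heavy      1181.91     808.44
#> 7  y'5^2+   heavy      1181.91     936.99
#> 8   b4^3+   heavy      1181.91     862.42
```

The product m/z columns are the reference transition values of the
assay; each heavy ion sits exactly `shift/charge` above its light
partner (Val +6.0138 Da on every y′ ion, Leu +7.0172 Da on b4).

```r
# DIA: simulate a run with one planted site, then search it
sim <- simulate_dia(sim_config(seed = 42))
ids <- search_dia(sim$run, fixture_proteins()[1, ])
tidy(ids)
#>              protein protein_site     backbone co_detected matched_fraction
#> 1 SYN_SUMO_SUBSTRATE            9 IISKIENHEGVR          19                1
#>   ppm_error                                     annotation
#> 1  2.553159 K9 conjugated with ELGMEEEDVIEVYQEQTGG remnant
glance(ids)   # the identification funnel
#>   n_peptides n_conjugates n_candidates n_hypotheses n_records
#> 1          9            3            1            1         1

# MRM: simulate at a known light/heavy ratio and recover it
mrm <- simulate_mrm(mrm_sim_config(seed = 7), tr, ratio = 0.5)
quantify_run(mrm$chromatograms, tr)$samples
#>   run_id peptide_id light_area heavy_area consensus_apex n_flagged     ratio
#> 1   run1  PKM2_K270    945.598   1878.918             30         0 0.5032672
```

The recovered ratio (0.503 against a planted 0.5) is the assay's
readout; all 19 diagnostic ions co-elute at the planted site and every
theoretical fragment is matched, so the record scores 1.0.

A thin command line (`inst/cli/branchms`) exposes the same steps as
subcommands: `digest`, `fragments`, `diagnose`, `search-dia`,
`design-mrm`, `quantify-mrm`, `simulate`.

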