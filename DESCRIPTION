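Package: branchms
Title: Branched-Peptide Mass Spectrometry: Diagnostic-Ion DIA Search and
    MRM Quantification of SUMO-Conjugated Peptides
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for mapping and quantifying SUMO conjugation sites by
    mass spectrometry. Builds branched (isopeptide-linked) peptides from a
    tryptic backbone and a SUMO remnant, generates their theoretical
    fragment ions (backbone b/y and remnant b/y' series), and implements a
    three-stage data-independent acquisition (SWATH) identification
    procedure: diagnostic-ion screening per isolation window, precursor
    mass matching against an in silico conjugate database, and MS/MS
    fragment mapping with site localization. Also designs multiple-reaction
    monitoring (MRM) transitions with heavy stable-isotope standards and
    quantifies light/heavy ratios by chromatographic peak-area integration.
    A seeded simulator produces DIA runs and MRM chromatograms with planted
    branched-peptide signals and a ground-truth manifest so every pipeline
    stage is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    mzR,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
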