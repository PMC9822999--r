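Package: spatmilieu
Title: Spatial Cytokine Milieus, Neighborhoods and Crosstalk in Multiplexed Tissue Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for multiplexed imaging (IMC) single-cell tables
    of tumor immune microenvironments, contrasting exhausted (IE1) and
    non-exhausted (IE2) immune environments. Provides negative-probe-calibrated
    per-cell cytokine expression calling with Benjamini-Hochberg control,
    detection of cytokine patches and their 30 micrometer milieus with
    per-image Fisher enrichment, permutation-based pairwise cell-type
    neighborhood analysis, k-nearest-neighbor composition profiling,
    myeloid functional gene-signature scoring, regularized ligand-receptor
    crosstalk scoring with per-patient immune-environment enrichment, and a
    ground-truth-bearing synthetic data generator emulating 1 mm x 1 mm
    imaging regions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
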