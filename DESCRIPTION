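Package: episcan
Title: Ome-Wide Association Mapping with Additive and Epistatic Effects
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Linear mixed model association mapping for genome-, transcriptome-
    and metabolome-wide marker panels that models both per-marker additive
    effects and pairwise additive-by-additive (epistatic) interaction effects.
    Builds trace-normalized additive and epistatic kinship matrices, estimates
    the three variance components by restricted maximum likelihood, and runs
    eigen-accelerated generalized least squares scans producing per-marker (1D)
    and per-marker-pair (2D) Wald tests. Includes leave-one-out predictability
    scoring of intermediate omic markers via the hat-matrix PRESS shortcut,
    cross-omics integration utilities (bin-level reduction, tissue-stratified
    top-n tables, weighted association networks), and a synthetic-data
    generator for recombinant inbred line genotypes and model-based traits.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    igraph,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
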