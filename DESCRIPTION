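Package: netsweep
Title: Dual-Modality Brain Network Analysis with Proportional-Threshold Sweeps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds weighted structural and functional brain connectivity
    networks from node time series and diffusion-derived matrices, sweeps
    proportional sparsity thresholds, and computes weighted global and nodal
    graph metrics with degree-preserving null-model normalization and
    area-under-the-curve summaries. Estimates per-subject structure-function
    coupling via rank-based inverse-normal rescaling, and runs the group-level
    statistical battery: covariate-adjusted general linear model contrasts with
    Bonferroni control over nodal families, permutation tests for coupling, and
    partial correlations with clinical scales. A seeded synthetic cohort
    generator with a small-world structural backbone and structurally coupled
    functional signals makes the whole pipeline testable end to end without
    patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
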