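Package: pairsurv
Title: Prognostic Gene-Pair Discovery from Single-Sample Differential
    Correlation Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies prognostic gene pairs in mutation-stratified tumor
    cohorts from single-sample network perturbation. For every pair of core
    genes, the change in Pearson correlation when one tumor sample is added
    to a normal reference panel (delta-PCC) is computed and screened by
    three significance criteria; patients are then stratified per pair by
    two-cluster partitioning of their delta-PCC values and ranked by
    log-rank tests with Benjamini-Hochberg correction and univariate Cox
    proportional-hazards models. Builds signed, weighted gene correlation
    networks enriched with per-gene prognostic annotations for two patient
    groups and compares them, performs two-group differential expression,
    and ships a fully seeded synthetic-cohort generator so the entire
    pipeline is testable without access to controlled clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
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
    stringr,
    survival,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
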