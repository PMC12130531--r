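Package: netdasc
Title: Signaling Network Dynamics and Differentially Activated Signaling
    Components
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds signed causal signaling networks from SIGNOR-style
    causal-interaction tables, formulates them as normalized logic-based
    ordinary differential equations on the unit interval, and simulates
    per-sample steady-state activity distributions by Monte Carlo over
    random initial conditions driven by expression-derived node
    capacities. Differentially activated signaling components (DASCs)
    between two phenotype groups are scored per cohort with a
    Kolmogorov-Smirnov statistic, an effect-size gate and
    Benjamini-Hochberg adjustment, then intersected across cohorts.
    Also provides the clinical-validation arithmetic used alongside such
    analyses (immunohistochemistry H-scores, 2x2 association tests,
    extreme-decile grouping), a synthetic-data generator with planted
    ground truth, and a reproducible pipeline driver with run manifests.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
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
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
LinkingTo: Rcpp
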