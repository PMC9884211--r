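Package: netpsy
Title: Network-Based Structural Validation of Psychometric Questionnaires
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Structural validation of ordinal psychometric questionnaires from
    the network perspective: redundancy detection and merging via Unique
    Variable Analysis (weighted topological overlap with an adaptive
    significance threshold), regularized partial-correlation network
    estimation (graphical lasso with extended-BIC model selection on
    polychoric or Pearson correlations), dimensionality assessment by
    spinglass community detection on signed networks, bootstrap exploratory
    graph analysis (median network, item stability, structural consistency),
    node-importance metrics (strength, expected influence, network loadings),
    and cross-cohort partition comparison via normalized and adjusted mutual
    information. Includes a synthetic ordinal-data generator with planted
    factor communities, redundant clones and cohort perturbations so the
    whole pipeline is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    clue,
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
LinkingTo: Rcpp
Suggests:
    mvtnorm,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
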