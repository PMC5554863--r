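Package: comdyn
Title: Cohesive and Disjoint Community Dynamics in Multilayer Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Quantifies how the nodes of a temporal (multilayer) network change
    community allegiance over time. Builds windowed wavelet-coherence networks
    from multivariate time series, detects communities by Louvain-style
    maximization of multilayer modularity with ordinal interlayer coupling, and
    computes node flexibility together with two complementary reconfiguration
    statistics: node cohesion (groups of nodes switching community together) and
    node disjointedness (lone switches). Includes a temporal layer-permutation
    null model, permutation tests with Benjamini-Hochberg false-discovery-rate
    control over a (gamma, omega) resolution grid, a robust double-exponential
    movement-time model for behavioural learning rates, and a synthetic-data
    generator with planted, ground-truth switching events.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    igraph,
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
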