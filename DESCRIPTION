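Package: adhesim
Title: Stochastic Models of Cytoneme Dynamics and Adhesion-Driven Cell Sorting
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Seeded stochastic simulators for two questions in developmental
    biophysics. A 1-D lattice model of cytoneme elongation, shrinkage and
    translocation in which homophilic trans interactions between aligned
    segments of neighboring cytonemes stabilise and bundle the filaments,
    with metrics for mean length, interaction counts, length-interaction
    correlation and a bundling index. A 2-D Voronoi/vertex Metropolis Monte
    Carlo model of a heterogeneous cell monolayer with areal elasticity,
    contractility and type-dependent differential adhesion, with
    neighbor-graph pattern statistics, honeycomb/checkerboard classification
    and adhesion-ratio sweeps that bracket the sorting transition. All
    user-facing functions take and return tidy data frames.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    igraph,
    jsonlite,
    readr,
    withr,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
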