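Package: elodin
Title: Ensembles of Logic-Based Dynamic Models for Signaling Network Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Data-driven inference of signaling-network topology and dynamics
    from perturbation time courses. Builds dense mutual-information networks
    from MIDAS-format data, samples bounded-in-degree scaffolds, parameterizes
    them as logic-based ordinary differential equation models (normalized Hill
    kinetics with multivariate polynomial interpolation of Boolean gates),
    trains them by seeded global optimization, prunes edges with a greedy
    AIC heuristic, and combines the trained models into robust ensemble
    trajectory predictions for untested perturbations. Includes precision-recall
    and RMSE evaluation against reference networks and a synthetic benchmark
    generator so the whole workflow is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
LinkingTo: Rcpp
Imports:
    Rcpp,
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    stringr,
    jsonlite,
    stats,
    utils,
    ggplot2,
    generics
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    yaml
Config/testthat/edition: 3
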