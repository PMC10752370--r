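Package: commsteer
Title: Model-Guided Steering of Synthetic Microbial Community Composition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing culture conditions that steer the taxonomic
    composition of defined bacterial communities. Implements logistic growth
    model fitting from plate-reader OD600 time series, design-of-experiments
    matrices (fractional factorial, definitive screening, Plackett-Burman),
    elastic-net response-surface ensembles with nested leave-one-out cross
    validation, a constrained system of logistic equations for inoculum
    optimization, generalized Lotka-Volterra inference with L1 regularization
    and bootstrap uncertainty, design-test-learn cycle orchestration, and
    gLV-guided design of subset communities with prescribed temporal
    variability across serial passages. A synthetic-data module generates
    study-shaped monoculture curves, designed community endpoints and passage
    series so the whole pipeline is testable without external data.
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
    glmnet,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    deSolve,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
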