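Package: stabsvm
Title: Stable Feature Selection with Ensemble L1-Norm Support Vector Machines
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Stability-aware biomarker selection for high-dimensional binary
    classification problems such as bulk or single-cell expression matrices.
    Fits L1-regularized squared-hinge support vector machines over an ensemble
    of class-stratified subsamples, eliminates zero-weight features
    iteratively, and aggregates the surviving sets into a per-feature
    stability score. A stability-ranked backward elimination with an
    RBF-kernel SVM locates the cross-validated-AUC-maximizing feature subset,
    and a Tanimoto-distance harness quantifies selection stability across
    random subsamples. Includes a seeded synthetic expression-data generator
    with planted informative features, delimited-text readers and writers, and
    a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    optparse,
    readr,
    rlang,
    tibble,
    withr,
    yaml,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
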