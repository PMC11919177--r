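Package: cognet
Title: Two-Wave Symptom Network Analysis with Regularized Gaussian
    Graphical Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for psychometric network analysis of depression,
    anxiety, and negative-cognition questionnaire data collected in two
    waves. Implements questionnaire scoring and record-validity
    filtering, sparse Gaussian graphical model estimation via a
    coordinate-descent graphical lasso with extended-BIC model
    selection, weighted-network centrality (strength, closeness,
    betweenness) and expected influence, nonparametric and case-drop
    bootstrap stability analysis with the correlation-stability
    coefficient, permutation-based network comparison, and a directed
    cross-lagged panel network fitted by penalized regression. Includes
    a synthetic two-wave data generator with known precision-matrix and
    transition-matrix ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    glmnet,
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
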