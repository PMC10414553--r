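Package: nof1var
Title: Vector Autoregression for Single-Patient Biomarker Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for n-of-1 (single subject) longitudinal biomarker
    analysis: regularization of irregularly sampled clinical measurements
    onto a fixed lag grid, multiple imputation by chained equations with
    truncated-normal conditional draws so laboratory values stay positive,
    vector autoregression with exogenous covariates and information-criterion
    lag-order selection, impulse-response functions with residual-bootstrap
    confidence bands, Rubin-rules pooling across imputations, pairwise
    Spearman association with pairwise-complete observations, and a synthetic
    panel generator that emulates a sparse multi-organ biomarker panel for
    validation of the whole chain.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
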