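Package: trfboost
Title: Sparse Temporal Response Function Estimation by Boosting
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Estimation of multivariate temporal response functions (mTRFs) from
    continuous electrophysiological recordings by coordinate-descent boosting with
    validation-based early stopping, including smooth basis windows, selective
    stopping, l1 and l2 error norms, k-fold cross-validation with held-out
    predictive power, and a ridge-regression reference estimator. Includes
    construction of auditory predictor variables (gammatone spectrograms, band
    binning, envelopes, nonlinear response scales, acoustic onset detection, and
    impulse or step predictors from event tables), mass-univariate cluster-based
    permutation statistics for group analysis, and a synthetic-data generator for
    correlated band predictors, ground-truth kernels, and pink noise.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    generics,
    jsonlite,
    Rcpp,
    signal,
    stats,
    tibble,
    tools,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    ggplot2,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
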