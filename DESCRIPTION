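Package: nmfcpd
Title: Change Point Detection in High-Dimensional Time Series Networks
    via Non-Negative Matrix Factorization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects multiple change points in the network (clustering)
    structure of multivariate, possibly high-dimensional (p >> T) time
    series.  Candidate change points are located by a binary search over
    the time index that compares generalized Kullback-Leibler losses of
    non-negative matrix factorizations fitted to overlapping padded data
    blocks, and are then pruned by a permutation test using Welch's
    t-statistic with Benjamini-Hochberg correction.  Between detected
    change points, stationary networks are estimated from NMF cluster
    co-membership via a consensus matrix.  Includes a piecewise-stationary
    block-covariance Gaussian simulator with abrupt and gradual regime
    changes and AR(1) noise, plus TP/FP and scaled Hausdorff evaluation
    utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    data.table,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
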