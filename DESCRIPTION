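Package: morphodev
Title: Normative Deviation Components of Brain Morphometry and Their
    Behavioral and Molecular Correlates
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: End-to-end analysis of inter-individual heterogeneity in
    regional brain morphometry (cortical thickness and subcortical volume).
    Harmonizes multi-site reference cohorts with empirical-Bayes
    location/scale adjustment, fits sex- and region-specific fractional
    polynomial normative growth models, scores patient deviations in RMSE
    units, decomposes the deviation matrix with orthonormal projective
    nonnegative matrix factorization (NNDSVD-initialized, split-half
    stability rank selection), links subject loadings to behavior with
    partial least squares (permutation and bootstrap-ratio inference), and
    relates component spatial maps to molecular predictor maps via
    dominance analysis, variogram-matched spatially autocorrelated
    surrogate nulls, and distance-dependent cross-validation. Includes a
    synthetic-cohort generator with planted ground truth for calibration
    and recovery testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    sva,
    withr,
    optparse
Config/testthat/edition: 3
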