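Package: lfci
Title: Intrinsic Dimension of Neural Manifolds via the Local Full Correlation Integral
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimation of the intrinsic dimension (ID) of point clouds such as
    neural population activity manifolds. Implements the full correlation
    integral (FCI) estimator, which fits the exact chord-distance law of a
    uniformly sampled hypersphere to the empirical correlation integral of
    centered and normalized data, and a local, multiscale version (lFCI) that
    runs the fit on k-nearest-neighbour patches across scales, discards
    neighbourhoods with sizable curvature (delta > 2) or comparatively poor fit
    quality, and aggregates the surviving local estimates into a histogram-mode
    ID with a percentile band. Also provides the standard comparison
    estimators (PCA variance thresholding, participation ratio, parallel
    analysis, correlation dimension, maximum-likelihood k-NN, Two-NN with
    decimation, cross-validated PCA projection), seeded synthetic manifold and
    latent-trajectory generators, and a rate-RNN simulator with a cognitive
    task battery for producing neural-manifold benchmarks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown,
    yaml
VignetteBuilder: knitr
Config/testthat/edition: 3
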