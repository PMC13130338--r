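Package: ccshape
Title: Two-Group Landmark-Based Statistical Shape Analysis
Version: 0.1.0
Authors@R:
    person("Analysis", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Landmark-based statistical shape analysis for comparing two
    groups of 2-D configurations, built around the mid-sagittal corpus
    callosum use case: TPS (tpsDig) and CSV landmark input, generalized
    Procrustes superimposition, Kendall shape-space Riemann distances and
    RMS-rho summaries, tangent-space projection with dimension reduction,
    a Box-M covariance-homogeneity gate into either a resampling James
    test or Hotelling's T-squared, thin-plate-spline deformation grids
    with Jacobian expansion factors, per-landmark dissimilarity ranking,
    and multivariate allometric regression of tangent coordinates on
    centroid size (Wilks' lambda, R-squared, MSE). Includes a seeded
    synthetic landmark generator emulating the assumed data structure so
    the full pipeline is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
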