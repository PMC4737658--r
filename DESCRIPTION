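Package: boldlag
Title: Temporal Lag Structure Analysis of Infra-Slow BOLD Fluctuations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates sub-sample temporal lags between pairs of BOLD-like
    voxel time series from lagged cross-covariance functions with parabolic
    interpolation, assembles anti-symmetric time-delay (TD) matrices and
    zero-lag functional-connectivity matrices, and reduces them to lag
    projections, seed-based lag maps and lag threads (spatial PCA of the
    column-centered TD matrix with maximum-likelihood dimensionality).
    Includes per-epoch preprocessing (linear detrending, zero-phase low-pass
    filtering, nuisance regression, frame censoring), permutation statistics
    for two-state contrasts (cluster-extent tests on lag projections,
    network-block Spearman and mean-lag tests, lag-SD contrast, FC-difference
    PCA), and a synthetic-data generator with planted fractional delays and
    propagation threads so the whole pipeline is exercised against known
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
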