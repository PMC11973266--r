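Package: pointspv
Title: Gaze-Contingent Simulated Prosthetic Vision with End-to-End
    Optimized Phosphene Encoding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for simulated prosthetic vision (SPV) research built
    around a point-sampling strategy: gaze-centered image patches are
    encoded by a fully convolutional network into binary 32x32 electrode
    activation maps, rendered as equally sized dot phosphenes on a fixed
    grid, and optimized end-to-end with a weighted combination of a
    mid-layer perceptual (feature-matching) loss against a frozen sighted
    reference network and a cross-entropy object-recognition loss, with
    straight-through gradients across the binarization.  Includes a
    synthetic scene and gaze-log generator, a Canny edge-detection
    baseline, an offline gaze-contingent presentation engine, and a
    behavioral metrics suite (accuracy, reaction time, saccade counts,
    Gaussian fixation-coverage statistics, group fixation heatmaps, and
    repeated-measures ANOVA).  The training engine is a compact CNN
    implementation (convolution, batch normalization, residual blocks,
    max pooling, Adam) written with RcppArmadillo.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    grDevices,
    tools,
    jsonlite,
    png,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    igraph
Config/testthat/edition: 3
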