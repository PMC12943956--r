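Package: rehabdtw
Title: Webcam-Based Movement Quality Scoring with Dynamic Time Warping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Toolkit for quantifying upper-limb movement quality from 2D
    pose-landmark streams recorded with a common webcam. Computes joint-angle
    trajectories via the law of cosines, smooths them, segments continuous
    movement into exercise repetitions, builds per-joint mean normal baseline
    trajectories from healthy-sample repetitions, and scores new repetitions
    0-100 through multi-dimensional dynamic time warping distance, Z-score
    standardization against the normal sample, and a hyperbolic score map.
    Includes a synthetic movement simulator that reproduces the study protocol
    (participants x exercises x sides x rounds) for validation, and an
    evaluation pipeline with subset splits, feature-set variants and
    significance tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
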