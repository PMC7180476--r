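Package: gaitwarp
Title: Template-Based Step Detection in Gyrometer Gait Signals with
    Dynamic Time Warping
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Detects gait stance phases (initial contact to final contact)
    in single-axis foot-mounted gyrometer recordings by sliding-window
    Pearson template matching followed by a banded dynamic-time-warping
    (DTW) boundary refinement.  Provides five strategies for constructing
    the step-template library (random selection, DTW medoid, linear
    fusion, DTW-aligned non-linear fusion, and a knowledge-based
    piecewise-affine prototype), event-level evaluation metrics
    (precision, recall, and start/end/duration timing errors in
    milliseconds), a seeded generator of annotated synthetic gait trials
    for end-to-end validation, and runners for the standard refinement,
    strategy-comparison, scan-width and distance-criterion experiments.
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
    withr
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
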