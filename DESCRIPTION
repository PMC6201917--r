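Package: gazeread
Title: Estimating Subjective Reading Comprehension from Eye Gaze
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating a reader's self-perceived (subjective)
    understanding of short texts from eye-tracking recordings. Provides
    readers and writers for raw gaze sample streams and session manifests,
    dispersion-threshold (I-DT) fixation detection with forward/backward
    saccade classification along the reading axis, four text-length
    normalized oculomotor features (fixations, forward and backward
    saccades per character, and the dispersion of saccade velocities),
    per-participant feature aggregation, and support-vector regression of
    mean self-rated understanding evaluated under leave-one-participant-out
    cross-validation against a comprehension-question-answer baseline. A
    calibrated synthetic reading-gaze simulator makes the full pipeline
    testable end to end without any eye-tracker data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
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
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
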