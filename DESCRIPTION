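Package: saccurv
Title: Saccade Curvature and Velocity-Profile Deviation Analysis for
    Natural-Viewing Gaze Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing saccadic eye movements recorded while
    viewing dynamic scenes. Implements blink excision, cubic-spline gap
    interpolation and Savitzky-Golay smoothing of 1 kHz gaze traces;
    velocity-threshold saccade detection with kinematic inclusion rules;
    median pointwise trajectory curvature; compressed-exponential
    velocity-profile fitting and a root-mean-square deviation score;
    adaptive frame-difference scene-cut detection with in-flight saccade
    flagging; and construction of a log10-polynomial, covariate-coded
    analysis table ready for mixed-effects modelling. A seeded synthetic
    generator produces ground-truth-labelled gaze sessions and video
    clips so the whole pipeline is testable without raw recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    png,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
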