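Package: oculopipe
Title: Automated Saccade, Blink and Pupil Analysis for Video-Based Eye Tracking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An automated analysis pipeline for high-frequency video-based eye
    tracking data. Parses EyeLink-style ASC exports or delimited sample tables
    into per-trial gaze traces, converts pixels to degrees of visual angle,
    re-references drift, and applies zero-phase boxcar smoothing before
    computing eye velocity and speed. Detects blinks from pupil-area dropout
    with trend flattening and dynamic-threshold extent refinement, detects
    saccades with per-trial dynamic velocity thresholds, absorbs post-saccadic
    oscillations for accurate endpoints, splits fused "boomerang" saccades,
    resolves blink-contaminated "blincades", and scores every saccade against
    a smoothing-spline main sequence. Computes fixation-locked pupillometric
    response metrics and classifies every trial of the interleaved
    pro/anti-saccade task (IPAST) into behavioural categories with session
    rate statistics. Includes a seeded synthetic-session generator with ground
    truth for end-to-end validation.
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
    purrr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    signal,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
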