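Package: okrplast
Title: Homeostatic Plasticity Analysis of the Optokinetic Reflex
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for optokinetic-reflex (OKR)
    entrainment experiments in larval amphibians. Generates triangular
    visual-motion stimulus profiles and cohorts of simulated eye-movement
    recordings obeying a parameterised homeostatic plasticity rule, renders
    and tracks phantom eye videos by moment-based ellipse fitting, converts
    raw traces into per-cycle peak-to-peak amplitude tables (200 Hz
    resampling, zero-phase low-pass Butterworth filtering, analytic cycle
    segmentation, conjugate averaging, velocity-based artifact exclusion),
    and quantifies homeostatic plasticity via the regression of
    training-induced amplitude change on initial amplitude (slope, R-squared
    and setpoint as the x-axis zero-intercept), with exact nonparametric
    tests and serial-section volume morphometry.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    readr,
    generics,
    signal,
    stats,
    utils,
    yaml,
    jsonlite,
    tiff,
    EBImage,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
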