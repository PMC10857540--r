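Package: fallrisk
Title: Wearable-Sensor Fall-Risk Assessment for Stroke Survivors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulation, segmentation, feature extraction and classification
    tools for inertial-sensor fall-risk assessment in stroke survivors. The
    package generates synthetic 60 Hz recordings from an 8-sensor body-worn
    array for a 10-task clinical battery (balance with eyes open/closed,
    timed-up-and-go, 10 m walk, five-repetition sit-to-stand, each with a
    motor-cognitive dual-task variant), detects gait events, timed-up-and-go
    phases and sit-to-stand cycles from the signals, extracts a 92-feature
    pool of sway, spatiotemporal and clinical measures, and evaluates
    high- versus low-fall-risk classifiers with heuristic forward feature
    selection under leave-one-subject-out cross-validation, including
    searches over reduced sensor configurations and test batteries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    purrr,
    randomForest,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
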