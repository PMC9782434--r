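Package: posturebench
Title: Simulation and Classifier Benchmarking for Reactive Postural Responses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for studying early detection of balance disorders in
    Parkinson's disease from body-worn inertial sensors during dynamic
    posturography. Generates sinusoidal yaw platform perturbations with
    sigmoidal on/off ramps and randomized trial schedules, simulates a
    virtual cohort of subjects (segment yaw transmission with configurable
    gain and phase, medio-lateral and antero-posterior sway, gravity and
    sensor noise in the body frame), extracts the 72 kinematic features
    (range of motion, spectral gain ratio and phase shift per body segment
    and test condition), cross-validates 13 classifier variants over 4
    classification experiments, and applies threshold gates plus a
    ROC-space goodness index to select best-performing classifiers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    signal,
    pracma,
    rpart,
    nnet,
    e1071,
    jsonlite,
    readr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    class,
    pROC
Config/testthat/edition: 3
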