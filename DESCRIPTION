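Package: boutwin
Title: Bout-Length-Informed Window Selection for Animal-Borne Sensor
    Behaviour Recognition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for recognising animal behaviours from collar-mounted
    inertial sensor streams using behaviour-specific sliding windows. The
    package run-length-encodes labelled recordings into behavioural bouts,
    computes per-window statistical features over a grid of window sizes,
    trains one-vs-all gradient-boosted classifiers with subject-independent
    cross-validation and SMOTE balancing, and fits a quadratic response of
    ROC AUC against window size to locate each behaviour's optimal window,
    testing whether it coincides with the behaviour's median bout length.
    Includes a synthetic collar-IMU simulator with controlled bout-length
    distributions for method development and validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    xgboost,
    yaml
Suggests:
    readr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
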