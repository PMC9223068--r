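Package: bedwatch
Title: Bedtime Fall Detection and Fall Prevention from Wearable and Bed-Pressure Sensors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for detecting and preventing night-time falls in older
    adults from two unobtrusive sensor streams: a waist-worn inertial
    measurement unit (tri-axial acceleration and angular velocity) and three
    pressure strips placed under the mattress. Implements a threshold-based
    fall state machine over the acceleration signal vector magnitude, a
    13-feature fall versus activity-of-daily-living classifier, a rule-based
    bed-position classifier with debouncing, a threshold movement detector
    for bed-exit intention, and the fusion of both streams into caregiver
    alarms. Includes a seeded simulator for falls, daily activities, bed
    exits and pressure patterns, and an evaluation module (confusion
    matrices, sensitivity, specificity, prevalence-weighted accuracy,
    independent-stage combination).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    jsonlite,
    e1071,
    stats,
    utils,
    generics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
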