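Package: postaki
Title: Validation, Updating, and Decision Analysis of Post-AKI Risk Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for externally validating clinical prediction models for
    outcomes after acute kidney injury (AKI), and for deciding who to follow
    up after hospital discharge. Ships two published logistic models - a
    90-day death-or-readmission model for all hospital survivors and a
    1-year CKD G4-G5 progression model for AKI survivors - as editable
    coefficient tables, scores cohorts on the prognostic-index scale,
    assesses discrimination (C statistic, Brier score) and calibration
    (predicted-to-observed ratio, calibration intercept and slope, decile
    tables), updates models by logistic recalibration or full refitting,
    compares follow-up strategies by net benefit over a grid of threshold
    probabilities (decision curve analysis), detects and stages AKI from
    serial creatinine under KDIGO-based rules, and mines post-discharge
    care-pathway event logs into directly-follows process maps. A synthetic
    cohort generator reproduces the covariate and outcome structure the
    analysis assumes so every stage can be exercised without access to
    patient-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
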