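Package: drscreen
Title: Diabetes Risk Score Screening, Validation, and Cohort Follow-Up
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for validating an additive diabetes risk score (FINDRISC)
    as a screening instrument for undiagnosed diabetes and prediabetes.
    Implements item-level scoring with unit-aware BMI computation, HbA1c
    classification, diagnostic accuracy across score cutoffs with exact
    Clopper-Pearson intervals, Youden-index and kappa based cutoff selection,
    ROC analysis with Hanley-McNeil confidence intervals, person-time
    incidence and odds-ratio analysis of a follow-up cohort, logistic
    regression with Hosmer-Lemeshow calibration, paired tests of behaviour
    change, sample-size calculators for ROC (Hanley-McNeil) and logistic
    regression (Demidenko) designs, exact integer reconstruction of rounded
    published summary tables, and a seeded synthetic-cohort generator for
    end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    e1071
Config/testthat/edition: 3
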