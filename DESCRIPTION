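Package: srai
Title: Scoring and Validation of the Sepsis Renal Angina Index
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Implements the renal angina index (RAI) and its sepsis
    modification (sRAI) for early prediction of severe acute kidney injury
    in children with septic shock, together with a complete external
    validation toolkit: KDIGO creatinine-based staging with baseline
    creatinine resolution (measured, height-based eGFR back-calculation, or
    age-based Pottel imputation), diagnostic test accuracy with exact
    Clopper-Pearson intervals and likelihood ratios, empirical ROC analysis
    with DeLong variance and the paired DeLong test, relative risks with
    log-Wald intervals, bivariate covariate screening, multivariable
    logistic models, and a calibrated synthetic-cohort generator so that
    every stage of the analysis is testable without patient-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
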