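Package: periotree
Title: Prognostic Modelling of Long-Term Tooth Loss After Periodontal Therapy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for prognostic modelling of 10-year tooth loss in
    periodontitis patients after active periodontal therapy. Implements a
    logistic model-based recursive partitioning tree with a per-patient
    random intercept (fitted by alternating score-test driven tree growth
    and adaptive Gauss-Hermite mixed-model estimation), patient-clustered
    bootstrap variable selection with asymmetric inclusion thresholds,
    patient-grouped k-fold cross-validation with Wilson confidence
    intervals, a calibrated synthetic cohort generator for clustered binary
    outcomes, and the published eight-group risk calculator for individual
    tooth prognosis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    pracma
Suggests:
    testthat (>= 3.0.0),
    lme4,
    withr
Config/testthat/edition: 3
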