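Package: vitalsep
Title: Sepsis Onset Prediction in the ICU from Minimal Vital-Sign Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for predicting sepsis onset in intensive
    care unit (ICU) stays from little more than bedside vital signs.
    Implements retrospective Sepsis-3 onset labeling (suspicion of infection
    from culture/antibiotic co-occurrence plus an acute two-point rise in an
    hourly SOFA score), hourly binning with carry-forward/back-fill
    imputation of electronic-health-record style observation streams,
    posterior-probability feature maps over the last two hours of data,
    cross-validated elastic-net classification across prediction horizons,
    comparator severity scores (SIRS, qSOFA, MEWS, SOFA, SAPS II),
    discrimination and operating-point evaluation, random observation-dropout
    robustness experiments, and a synthetic ICU cohort generator so that
    every stage can be exercised without access to restricted clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    glmnet,
    jsonlite,
    stats,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
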