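Package: liradsaf
Title: Ancillary-Feature Optimization of LI-RADS v2018 for LR-3/4 Liver Lesions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study how ancillary imaging features (AFs) can sharpen
    the LI-RADS v2018 categorization of indeterminate (LR-3/LR-4) liver
    observations on MRI. Provides a synthetic lesion-cohort generator
    parameterized by published feature prevalences, the major-feature
    decision table assigning LR-3/4/5 categories, statistical screening of
    discriminative AF panels (contingency tests, Woolf odds-ratio intervals,
    logistic regression by iteratively reweighted least squares, forward
    stepwise selection), the one-step upgrade/degrade/retain category
    adjustment rule, and diagnostic-performance evaluation (sensitivity,
    specificity, Cohen's kappa, McNemar tests, stratified internal
    validation with ROC/AUC, calibration and decision-curve analysis).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
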