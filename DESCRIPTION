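Package: breathdx
Title: Breath VOC Biomarker Screening and Diagnostic Modelling for Thoracic Lesions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reproducible pipeline for building diagnostic classifiers from
    exhaled-breath volatile organic compound (VOC) profiles measured by
    GC-MS. Implements signal-to-noise based quality control of peak-area
    matrices, log10/median/z-score normalization, dual-criteria biomarker
    screening (Wilcoxon rank-sum p-values plus OPLS-DA variable importance
    in projection), AUC-ranked forward feature selection with stratified
    cross-validation, grid-searched regularized logistic regression with a
    Youden-index decision threshold, and evaluation statistics: ROC AUC with
    DeLong intervals, Wilson score intervals for proportions, the DeLong
    test for paired AUC comparison, McNemar's test against serum tumor
    marker panels, and paired pre/post-operative score monitoring. Includes
    a synthetic breath-cohort generator with planted differential compounds
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    pROC,
    mixOmics,
    withr
Config/testthat/edition: 3
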