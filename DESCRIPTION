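Package: gcpanel
Title: Composite Gene-Expression Panel Scoring for Glucocorticoid Resistance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and evaluating a 12-gene whole-blood
    expression score that predicts glucocorticoid (GC) resistance in
    multiple sclerosis relapses. Implements qPCR relative-expression
    normalization against a housekeeping gene, empirical ROC curves with
    cut-off selection under a specificity constraint, directional
    binarization of gene expression into a 0-12 composite score,
    score-level ROC thresholding, baseline cohort statistics (chi-square,
    Mann-Whitney U) and confounder-adjusted logistic regression, a
    differential-expression prefilter with Benjamini-Hochberg correction,
    and a calibrated latent-liability synthetic cohort generator so the
    full pipeline is testable without patient data. Includes an exact
    Poisson-binomial score distribution as an independence-model oracle.
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
    pROC,
    optparse,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
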