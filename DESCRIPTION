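Package: ventsig
Title: Mechanical-Ventilation Signatures in Bulk Tissue Transcriptomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects and explains mechanical-ventilation (MV) expression
    signatures in bulk RNA-seq cohorts with GTEx-style covariates. Implements
    a two-step confounder residualization that removes batch, age, sex and
    ischemic-time effects without absorbing the ventilation signal that is
    correlated with ischemic time, stratified cross-validated classification
    of ventilation status (gradient boosting, random forest, neural network),
    exact Shapley-value feature attribution for tree ensembles,
    hypergeometric gene-set over-representation with Benjamini-Hochberg
    adjustment, and a seeded synthetic-cohort generator that emulates the
    covariate and effect structure of GTEx tissues so the whole pipeline is
    testable without any download.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    ranger,
    stats,
    utils,
    xgboost
Suggests:
    limma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
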