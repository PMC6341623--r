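Package: MSIscore
Title: Microsatellite Instability Prediction from Gene Expression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Predicts tumor microsatellite instability (MSI) status from bulk
    log2 gene expression. Implements an MMR Loss score that detects loss of
    expression in the mismatch-repair genes MLH1, MSH2, MSH6 and PMS2, a
    10-gene weighted linear Hypermutation Predictor score, and a combined MSI
    Predictor p-value with evidence truncation. Includes unsupervised
    cross-platform calibration of reference means via two-component Gaussian
    mixture models, reference training from labeled cohorts, a seeded
    synthetic-cohort generator, and ROC / Wilson-interval evaluation tools.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    limma,
    jsonlite,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0),
    mclust,
    pROC
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'MSIscore-package.R'
    'expression-io.R'
    'scoring.R'
    'calibration.R'
    'evaluation.R'
    'weights.R'
    'synthetic.R'
    'serialize.R'
    'cli.R'
    'reference-training.R'
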