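Package: soacqspr
Title: QSPR Modelling of Singlet-Oxygen-Scavenging Activity
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A reproducible pipeline for quantitative structure-property
    modelling of singlet oxygen absorbance capacity (SOAC). Featurizes small
    molecules into molecular descriptors and Morgan (ECFP) fingerprint bits,
    prunes descriptors by zero variance, duplication and pairwise correlation,
    evaluates a suite of regression families (gradient boosting, random
    forest, AdaBoost.R2, lasso, optionally a small neural network) under a
    fixed train/test split protocol with leave-one-out cross-validation, and
    aggregates per-model feature importances into a rank-score consensus.
    Ships a synthetic-data generator with planted ground truth so the whole
    pipeline is testable end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    glmnet,
    randomForest,
    xgboost,
    rpart,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    ChemmineOB,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'FeatureTable.R'
    'utils.R'
    'backends.R'
    'models.R'
    'experiment.R'
    'fingerprint.R'
    'featurize.R'
    'importance.R'
    'select.R'
    'synthetic.R'
    'pipeline.R'
    'targets.R'
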