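Package: ConfQSAR
Title: Collaborative QSAR Modeling with Confidential Model Exchange
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds company-local binary PLS-DA activity models (AMES
    mutagenicity style) on feature-typed circular fingerprints, exports
    them as structure-free "confidential" archives carrying only model
    coefficients and per-feature scaling statistics, and recombines
    archives from several partners into ensemble metamodels (logical OR,
    majority voting, or trained RF/SVM/XGBoost combiners). Includes the
    honest-broker deduplication protocol for building an untainted common
    validation set (InChIKey and Tanimoto matching), a synthetic-object
    PCA view of chemical-space coverage for locked models, and a
    fragment-grammar generator of labeled chemical series for simulation
    studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    ChemmineR,
    ChemmineOB,
    igraph,
    randomForest,
    e1071,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    mixOmics,
    ggplot2,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
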