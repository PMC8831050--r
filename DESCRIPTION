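Package: UPDRSens
Title: Cluster-Ensemble Support Vector Regression for UPDRS Telemonitoring
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Hybrid machine-learning pipeline for predicting Parkinson's
    disease progression (Motor-UPDRS and Total-UPDRS) from telemonitoring
    voice features. Combines iterative low-rank SVD imputation of missing
    feature values, base clusterings by expectation-maximization Gaussian
    mixtures and self-organizing maps, consensus fusion of cluster
    ensembles (co-association/CSPA, balanced minimal hyperedge-cut HGPA,
    and Hungarian-aligned majority voting), principal-component
    decorrelation, and per-cluster bagged ensembles of RBF-kernel support
    vector regressors, evaluated by RMSE, MAE, Willmott's index of
    agreement, prediction accuracy and adjusted R-squared. Includes a
    synthetic telemonitoring data generator with known cluster structure
    so every stage can be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    e1071,
    jsonlite,
    yaml,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'utils.R'
    'dataio.R'
    'synthetic.R'
    'impute.R'
    'reduce.R'
    'cluster.R'
    'consensus.R'
    'regress.R'
    'evaluate.R'
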