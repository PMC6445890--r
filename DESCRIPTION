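Package: abrf
Title: Two-Stage Feature Selection and Random-Forest Classification of
    Anticancer Drug Sensitivity
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Predicts binary anticancer drug sensitivity (IC50 below or
    above the per-drug median) of cancer cell lines from gene-expression,
    copy-number-alteration and single-nucleotide-mutation feature tables.
    Implements weighted-KNN imputation of missing IC50/CNA/SNV values with
    distances taken on the complete expression profiles, a two-stage
    feature selection -- an unsupervised single-hidden-layer tanh
    autoencoder screen ranked by Gedeon proportional weight contributions
    followed by Boruta shadow-feature selection with mean-decrease-accuracy
    Z scores -- and a random forest of CARTs grown on ceiling(0.632 N)
    subsamples, wrapped in EasyEnsemble undersampling for drugs with
    imbalance ratio above 2. Performance is reported by stratified 10-fold
    cross-validation (ACC, recall, specificity, F1, MCC, AUC), and selected
    features are assessed by Wilcoxon rank-sum or Fisher exact tests.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    data.table,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    randomForest,
    pROC,
    optparse
Config/testthat/edition: 3
biocViews: Classification, FeatureExtraction, Pharmacogenomics
RoxygenNote: 7.3.3
Collate: 
    'abrf-package.R'
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'autoencoder.R'
    'forest.R'
    'boruta.R'
    'evaluation.R'
    'io.R'
    'labeling.R'
    'synthetic.R'
    'pipeline.R'
    'preprocess.R'
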