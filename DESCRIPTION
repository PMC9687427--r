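Package: sncvote
Title: Ensemble Hard-Voting Biomarker Discovery from Small RNA Counts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for small non-coding RNA (miRNA/piRNA) count
    data from spent blastocyst medium: negative-binomial count simulation,
    size-class filtering and fractional counting of multi-mapped reads,
    from-scratch trimmed-mean-of-M-values (TMM) normalization with CPM
    scaling, ensemble feature selection (gradient boosting, L1-regularized
    logistic regression, extremely randomized trees) combined by top-k hard
    voting with one-way ANOVA arbitration, leave-one-out hard-voting
    classification (SVM, random forest, SGD linear classifier),
    hierarchical-clustering anomaly detection, and evaluation metrics
    (confusion metrics, ROC/AUC, precision-recall, accuracy versus number
    of features).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    glmnet,
    xgboost,
    ranger,
    e1071,
    randomForest,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    edgeR,
    pROC,
    MASS
Config/testthat/edition: 3
RoxygenNote: 7.3.3
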