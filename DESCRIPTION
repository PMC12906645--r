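Package: gbwoem
Title: Gradient-Based Weight-Optimized Ensemble Models for Binary Clinical Classification
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Soft-voting ensembles of five tuned base classifiers (logistic
    regression, decision tree, random forest, k-nearest neighbours, multi-layer
    perceptron) whose per-model weights are fitted by gradient descent on an
    epsilon-stabilized binary cross-entropy loss with patience-based early
    stopping and best-weight restoration. Includes both random-normalized and
    uniform weight initialization, exhaustive search over all base-model
    subsets of size two or more, leakage-free preprocessing for clinical
    tabular data (invalid-zero imputation, one-hot encoding, min-max scaling,
    stratified three-way splitting), trapezoidal ROC/AUC evaluation, and a
    seeded synthetic-data generator emulating imbalanced healthcare tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    withr,
    readr,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    stats,
    utils,
    rpart,
    randomForest,
    nnet,
    class
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
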