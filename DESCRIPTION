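Package: mirnadx
Title: Sequence- and Annotation-Based Classification of Disease-Associated miRNAs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: An end-to-end pipeline for discriminating disease-associated
    microRNAs from random ones using sequence descriptors (length,
    composition, tetramer motifs, hydrogen-bond count, mean residue mass),
    filtered gene-target and KEGG-pathway annotations encoded as one-hot
    features, correlation-based feature subset selection (CFS with
    best-first search), and a bank of seven classifiers including naive
    Bayes, a Hoeffding (VFDT-style) tree, AdaBoost.M1, random tree/forest,
    a multilayer perceptron, and a five-layer sequential neural network.
    Includes stratified k-fold cross-validation with ROC/AUC reporting,
    an independent-holdout validation protocol, and a reproducible
    synthetic cohort generator for benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    foreign,
    jsonlite,
    yaml,
    nnet,
    randomForest,
    rpart,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
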