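Package: gaborleaf
Title: Log-Gabor Filter Banks Fused into Dense Convolutional Networks for Leaf Texture Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for identifying plants from leaf texture with a hybrid of
    handcrafted and learned features. Builds 2-D Log-Gabor filter banks in the
    frequency domain, constructs DenseNet-style convolutional classifiers whose
    transition layers are fused with pooled Log-Gabor magnitude maps, and
    trains them with a stratified split, early stopping and best-weight
    checkpointing. Includes per-class one-vs-rest confusion metrics (accuracy,
    recall, precision, fall-out, F1), a benchmark harness that evaluates
    fixed-length image features under six classical supervised classifiers,
    and a seeded generator of oriented leaf-like synthetic textures so the
    whole pipeline is testable without external image data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    png,
    withr,
    e1071,
    class,
    rpart,
    nnet,
    randomForest
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
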