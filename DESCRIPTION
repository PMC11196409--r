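Package: braincdnet
Title: Concatenated Convolutional Networks with Nimble Sharpening for Brain MRI Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements the BrainCDNet workflow for binary and multiclass
    classification of 2-D brain MRI slices: a Nimble edge-sharpening filter,
    a declarative specification of the concatenated three-block convolutional
    architecture with an exact trainable/non-trainable parameter audit, a
    self-contained training engine (SELU/GELU activations, batch
    normalization, global average pooling, Adam), stratified k-fold and
    holdout validation, confusion-matrix and one-vs-rest ROC/AUC metrics, and
    a synthetic MRI phantom generator so the full pipeline can be exercised
    without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    withr,
    EBImage,
    png,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
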