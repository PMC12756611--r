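Package: starmanet
Title: Star-Shaped Multi-Scale Attention Networks for Medical Image Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements the star-shaped multi-scale attention (StarMA) mechanism
    and the StarMA Net convolutional backbone for 2-D medical image
    classification, together with a layer-by-layer parameter and
    multiply-accumulate accountant, a full evaluation-metrics suite (accuracy,
    precision, sensitivity, specificity, F1, MCC, Cohen's kappa, ROC/AUC),
    gradient-weighted class-activation (Grad-CAM) visualization, a deterministic
    synthetic lesion-image generator, and a seeded training and evaluation
    pipeline. The network forward and backward passes are implemented on BLAS
    matrix operations with a compiled im2col kernel, so models train and
    evaluate on CPU with no external deep-learning framework.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    methods,
    stats,
    utils,
    grDevices,
    jsonlite,
    yaml,
    png,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
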