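Package: optconform
Title: Optimizer Weight Conformance and Transfer Learning on Synthetic
    Regulatory-Network Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation-based introspection of stochastic optimizers and a
    desk-scale transfer-learning evaluation for biological network-image
    classification. Implements from-scratch stochastic gradient descent,
    RMSprop and Adam fits of a two-parameter linear model to four benchmark
    generative functions; pairwise model-conformance distances between the
    fitted models with a nine-run significance protocol; a synthetic
    generator for two-class single-cell gene regulatory network style
    raster images; and a small convolutional network supporting
    feature-extraction and fine-tuning transfer modes, evaluated with
    balanced accuracy, precision, recall and F1 under five-fold
    cross-validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    igraph,
    jsonlite,
    png,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
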