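Package: omicsgsn
Title: Image-Based Multi-Omics Integration via PaCMAP Gene-Similarity Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrates gene expression, DNA methylation and copy-number
    alteration profiles into per-sample RGB images and classifies them with a
    compact convolutional neural network. Genes are embedded into two
    dimensions with a from-scratch implementation of PaCMAP (pairwise
    controlled manifold approximation: neighbor, mid-near and further pair
    losses under a three-phase weight schedule), the embedding defines a fixed
    gene-similarity-network image template, each sample's omics values colour
    circular zones around the gene positions (red = expression, green =
    methylation, blue = CNA), and the images are classified by a three-block
    CNN trained with Adam. Includes preprocessing filters, a seeded synthetic
    multi-omics generator, evaluation metrics (accuracy, precision, recall,
    F1, one-vs-rest AUC) and an end-to-end pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    generics,
    ggplot2,
    grDevices,
    jsonlite,
    png,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
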