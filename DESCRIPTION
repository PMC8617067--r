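Package: cellcount
Title: Segmentation-Based Cell Counting for Fluorescence Microscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for counting fluorescently labelled cells
    in microscopy images. Provides four fully-convolutional segmentation
    network builders (U-Net, small U-Net, residual U-Net and the cell
    residual U-Net with a learned colorspace convolution and a wide-field
    5x5 residual bottleneck), an additive border-penalty weight-map
    construction with a weighted binary cross-entropy loss, a dataset
    pipeline (splitting, overlapping crop tiling, geometric and photometric
    augmentation and artifact oversampling), heatmap post-processing with
    watershed splitting of touching cells, detection and counting metrics
    with knee-point threshold selection, and a seeded synthetic
    fluorescence-image generator so the whole pipeline is testable at desk
    scale. The network engine (convolution, transposed convolution, pooling,
    batch normalization and their gradients) is implemented natively in C++.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    png,
    Rcpp,
    stats,
    tiff,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
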