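Package: frycount
Title: Single-Keypoint Heatmap Counting of Dense Small Objects
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Counting and locating small, densely packed biological objects
    (fish fry, shrimp larvae, cells) from still images using a single-keypoint
    heatmap approach. Provides Gaussian target encoding of head-point
    annotations, a dual-branch high-resolution convolutional feature extractor
    with a twin transposed-convolution head that predicts a full-resolution
    keypoint heatmap, a max-pool local-peak decoder that turns heatmaps into
    counts with coordinates, counting metrics (relative-error accuracy, RMSE,
    MAE) with per-batch and per-density reporting, Labelme-style point
    annotation I/O with batch manifests, and a synthetic fry-scene simulator so
    the whole pipeline can be trained and evaluated without external data. The
    network layers (convolution, transposed convolution, batch normalisation)
    and their gradients are implemented natively with fast BLAS-backed kernels.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    jsonlite,
    yaml,
    png,
    EBImage
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
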