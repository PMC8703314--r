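Package: flairseg
Title: Weakly Supervised Brain Tumor Segmentation from CNN Feature-Map
    Gradients
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Two-stage pipeline for FLAIR MRI slices: a compact 18-layer
    convolutional neural network classifies a slice as tumor or not tumor,
    and, for tumor slices, a segmentation mask is derived without any
    pixel-level supervision by weighting the last convolution layer's
    feature maps with the mean and maximum of their spatial intensity
    gradients, averaging, thresholding and morphological post-processing.
    Includes a NIfTI slice reader, z-score normalization and geometric
    augmentation, Dice-based evaluation, a synthetic FLAIR-like phantom
    generator with paired ground-truth lesion masks, and a command-line
    interface. The network engine (im2col convolution, max pooling, Adam)
    is implemented in C++ via RcppArmadillo.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    EBImage,
    png,
    yaml,
    jsonlite,
    tibble,
    dplyr,
    rlang,
    generics,
    ggplot2,
    grDevices,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    optparse
Config/testthat/edition: 3
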