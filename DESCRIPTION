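Package: hippunet
Title: Deeply Supervised 3D U-Net Toolkit for Hippocampus Subfield Segmentation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for training and evaluating deeply supervised 3D
    encoder-decoder networks that segment hippocampus subfields from paired
    T1-weighted and T2-weighted MR volumes. Implements a family of
    differentiable region-overlap training objectives (Dice, generalized
    Dice, Jaccard and generalized Jaccard losses, plus categorical
    cross-entropy), a multi-resolution U-Net variant with deep supervision
    and coarse-to-fine output feedback, prediction with either stored or
    sample-specific batch-normalization statistics, the accompanying
    augmentation suite (left-right flip pooling, random smoothing and
    sharpening, mixup), cropping and intensity-normalization preprocessing
    with NIfTI input and output, Dice-based K-fold evaluation, and a
    synthetic two-channel phantom generator so the complete pipeline can be
    exercised without access to manually labelled MRI datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    tibble,
    dplyr,
    tidyr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
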