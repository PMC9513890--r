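Package: cascseg
Title: Coarse-to-Fine Cascaded 3D Segmentation of Saccular Aneurysms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Cascaded coarse-to-fine convolutional segmentation of saccular
    aneurysms in 3D angiographic volumes. A lightweight coarse network
    localizes candidate lesions on the whole vessel volume; cubic volumes of
    interest are cropped around each candidate and segmented by a dual-channel
    fine network that sees the vessel image together with its Sobel contour
    image, trained with a weighted soft-dice loss that up-weights poorly
    overlapping predictions. Includes a synthetic vascular phantom generator
    (tubular vessels with attached saccular bulges), the full preprocessing
    and eightfold augmentation chain, volume-of-interest geometry, evaluation
    metrics (dice, Hausdorff distance in mm, volumetric similarity), and a
    self-contained trainable 3D network engine, so the whole pipeline runs
    end-to-end on a CPU with no external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    Rcpp,
    jsonlite,
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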