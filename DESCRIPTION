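Package: znet3d
Title: Densely Connected 3D Encoder-Decoder Networks for Multimodal
    Brain Tumor Segmentation
Version: 0.1.0
Authors@R:
    person("znet3d", "developers", email = "znet3d@example.org",
           role = c("aut", "cre"))
Description: An end-to-end pipeline for volumetric brain-tumor
    segmentation from multimodal magnetic resonance imaging in the
    BraTS layout: NIfTI-1 input/output, per-modality min-max intensity
    normalization, trilinear/nearest-neighbour volume resizing,
    derivation of the nested whole-tumor, tumor-core and
    enhancing-tumor binary masks from the 4-valued expert labeling,
    in-plane rotation augmentation, a densely connected 3D
    encoder-decoder convolutional network ("Z-net") with hand-verified
    forward and backward passes, ADAM training under a binary
    cross-entropy loss, dice-coefficient evaluation, and a synthetic
    phantom generator so the whole pipeline is testable without any
    data download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    grDevices,
    graphics,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
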