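Package: femurseg
Title: Proximal Femur MRI Segmentation with Convolutional Encoder-Decoder Networks
Version: 0.1.0
Authors@R:
    person("femurseg", "developers", email = "femurseg@example.org", role = c("aut", "cre"))
Description: Toolkit for automatic segmentation of the proximal femur from
    volumetric structural MR images using 2D and 3D encoder-decoder
    convolutional neural networks, including an optional dilated-convolution
    pyramid at the center layer, a class-re-weighted cross-entropy loss,
    mirrored tiled inference for unpadded networks, largest-connected-component
    post-processing, precision-recall operating-point selection, and a full
    overlap and surface-distance evaluation suite with paired model
    comparison statistics. Ships a parametric femur-like phantom generator
    with paired ground-truth masks so the whole pipeline can be exercised and
    tested without access to clinical data, plus minimal NIfTI-1 volume I/O
    and a command-line interface covering simulation, training,
    cross-validation, prediction, evaluation and model comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    withr,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
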