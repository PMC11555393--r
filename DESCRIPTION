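Package: mifnet
Title: Multi-Scale Interleaved-Fusion Networks for Lung-Nodule Patch
    Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Implements the MIFNet family of lightweight multi-scale
    interleaved-fusion convolutional networks for benign/malignant
    classification of 50x50 lung-nodule CT patches, together with an
    analytic complexity calculus (output sizes, receptive fields,
    parameter and FLOP counts), a LUNA16-style MetaImage preprocessing
    pipeline (world-to-voxel conversion, Hounsfield windowing, patch
    extraction, class rebalancing), a synthetic phantom-scan and patch
    generator for desk-scale testing, and a seeded training and
    evaluation engine (ADAM, SGDM and RMSprop) with compiled kernels.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    png,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
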