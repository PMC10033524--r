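Package: bladderseg
Title: Bladder Wall and Tumor Segmentation on T2-Weighted MRI with
    Progressive-Dilated 3D U-Nets
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Fully automated volumetric segmentation of the bladder wall and
    bladder tumor on 3D T2-weighted MRI. Provides NRRD volume input/output,
    fixed region-of-interest preprocessing with intensity normalization and
    three-class label encoding, rotation/flip/elastic data augmentation under
    two multiplication scenarios, a family of 4/5/6-level 3D U-Net
    architectures with progressive dilated convolutions (trained from scratch
    with Adam and categorical cross-entropy, validation-Dice checkpointing),
    bilateral-filter post-processing, and multi-class Dice evaluation.
    Includes a synthetic bladder-phantom generator so the whole pipeline can
    be exercised end to end without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
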