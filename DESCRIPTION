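Package: plaquenet
Title: Dual-Branch Segmentation and Diameter Regression for Carotid
    Plaque Ultrasound
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Joint semantic segmentation and long/short diameter regression of
    carotid plaques in B-mode ultrasound images. Implements a U-Net style
    encoder-decoder with a multi-layer efficient channel attention (ECA) module
    at every encoder stage and a size-regression branch fed from the deepest
    encoder features, trained with a weighted joint cross-entropy plus
    mean-squared-error loss. Ships a speckle-noise ultrasound phantom
    generator with exactly known masks and diameters, a manifest-driven
    split/augmentation pipeline, a segmentation and regression metric suite
    (accuracy, mean IoU, background-excluded IoU, Dice, MSE, MAE, R squared),
    Feret-diameter morphometry of binary masks, and a training harness with
    best-on-validation checkpointing, early stopping and repeated-run
    aggregation, including a segment-then-measure baseline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    EBImage,
    png,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
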