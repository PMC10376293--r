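Package: capriDetect
Title: Small-Target Goat Face Detection with Context Aggregation and
    Feature-Complementary Fusion
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for detecting small (<= 50 pixel) goat faces in
    livestock imagery. Implements an anchor-based one-stage detector with
    a multi-rate dilated-convolution context module, cross-resolution
    feature-complementary fusion with absolute-difference noise
    suppression, and a width-height decomposed CIoU bounding-box
    regression loss, together with Pascal VOC annotation I/O, mosaic and
    mixup augmentation, a seeded synthetic goat-scene generator,
    IoU-matched detection metrics (precision, recall, F1, average
    precision), anchor clustering under the 1-IoU metric, and Friedman /
    Nemenyi rank statistics for model comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    xml2,
    yaml,
    png,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
biocViews: ImageProcessing, Classification, Software
RoxygenNote: 7.3.3
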