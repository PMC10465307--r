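Package: berryseg
Title: Instance Segmentation and Counting of Grape Berries in Single Bunches
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detection, instance segmentation and counting of grape berries in
    images of single bunches, aimed at berry-thinning decision support. Implements
    a Swin-Transformer-Tiny feature pyramid backbone, a four-level adaptively
    spatial feature fusion (ASFF) neck, a region proposal network with
    berry-scale-optimized anchors, Gaussian Soft-NMS candidate filtering,
    two-stage box and mask heads, COCO-style average-precision evaluation, and
    linear calibration of predicted against manually counted berries per bunch.
    All network layers are implemented natively in R with dense matrix algebra;
    a built-in synthetic bunch generator renders occluding elliptical berries
    with exact COCO annotations so that the full pipeline is testable end to end
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    png,
    yaml,
    ggplot2,
    generics,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
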