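Package: pestkit
Title: Building Blocks for Small-Object Pest Detection Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Implements the bespoke components of a lightweight single-stage
    pest-detection pipeline, testable end-to-end on synthetic labeled images
    without a GPU: a point-line-distance bounding-box regression loss (PLDIoU)
    with analytic gradients, convolutional block attention (CBAM) on feature
    maps, Mosaic/Mosaic-9/Mixup augmentation with exact bounding-box
    remapping, K-means anchor-box optimization under a 1-IoU distance,
    PASCAL VOC XML and YOLO text annotation input/output with a two-stage
    dataset split, and a full detection-evaluation stack (precision, recall,
    average precision, mAP, F1, mean detection time). A synthetic-fixtures
    module generates labeled scenes, planted evaluation sets with known
    metric values, box pairs, and clustered box-dimension mixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    png,
    stats,
    tools,
    utils,
    withr,
    xml2
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
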