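Package: rdblocks
Title: Lightweight Attention Blocks and Evaluation Tools for Rice Disease Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Building blocks, model assembly and evaluation tools for a
    lightweight single-stage rice-disease detector. Implements decomposed
    large-separable-kernel attention (LSKAC) with closed-form parameter and
    FLOP accounting, the SPPFLKC pooling-attention block, CAFormer/CGLU
    spatial-channel reconstruction units, the CSCBAM joint channel-spatial
    attention, and a small-object detection head, on top of a compact
    CPU convolutional-network engine with reverse-mode differentiation.
    Ships a YOLO-format dataset pipeline with stratified splitting and
    augmentation, a deterministic synthetic paddy-scene generator for three
    foliar disease classes (Brown Spot, Rice Blast, Bacterial Blight), and a
    detection-metrics evaluator (per-class AP, mAP50, mAP50-95, confusion
    matrix) with COCO-style 101-point interpolation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    png,
    stats,
    utils,
    grDevices
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jpeg,
    knitr
Config/testthat/edition: 3
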