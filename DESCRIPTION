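Package: fluokernel
Title: Machine-Vision Toolkit for Fluorescent Maize Kernel Phenotyping and Sorting
Version: 0.1.0
Authors@R:
    person("fluokernel", "developers", email = "fluokernel@example.org",
           role = c("aut", "cre"))
Description: Tools for building and evaluating machine-vision pipelines that
    separate fluorescently labelled maize kernels (mCherry/DsRed marker lines)
    from non-fluorescent kernels. Provides a seeded synthetic scene generator
    with per-kernel ground truth; a classical segmentation chain (grayscale,
    median filter, Laplacian sharpening, Otsu binarization with disk
    morphology, marker-controlled watershed); RGB/HSV colour-moment feature
    extraction and a moment-threshold classifier; detection-style image
    augmentation (gamma transform, HSV jitter, mosaic composition); bounding
    box geometry with IoU/GIoU/CIoU losses; precision-recall evaluation
    metrics with average precision; a forward-pass convolutional block
    attention module (CBAM); a conveyor-belt sorting simulator; and readers
    and writers for YOLO-txt and Pascal-VOC XML labels plus PNG/PNM rasters.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    grDevices,
    stats,
    utils,
    jsonlite,
    xml2,
    yaml,
    png,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
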