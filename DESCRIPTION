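Package: greenpoly
Title: Automatic Polygon Annotation of Plants from Bounding Boxes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Converts bounding-box labels of plants in field-crop images into
    polygonal segmentation masks. Candidate masks are produced by iteratively
    narrowing the accepted hue range in HSV colour space; each candidate is
    scored with an integral contour-quality metric combining the dynamics of
    contour area and of the contour's bounding rectangle, and the mask kept is
    the last stable one before the first significant score drop. Includes
    Pascal VOC annotation ingestion and cleaning, morphological mask
    refinement, Douglas-Peucker polygon simplification, YOLO segmentation
    label export, IoU/Dice evaluation with a weight-sweep harness, four
    classical baseline segmenters, and a seeded synthetic field-scene
    generator with exact ground-truth masks.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    EBImage,
    png,
    xml2,
    yaml,
    grDevices,
    graphics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
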