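Package: croprows
Title: Crop Row Detection in Field Images by Rectification, Density
    Clustering and Robust Line Fitting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects crop rows in RGB images of agricultural fields for
    vision-based vehicle guidance. The detector rectifies a region of
    interest with a four-point planar homography so rows become parallel
    and near-vertical, segments vegetation with the Excess Green index and
    Otsu thresholding, cleans the mask morphologically, groups foreground
    pixels into candidate rows by density-based clustering with geometric
    repair rules (iterative outlier peeling, adjacent-cluster pruning),
    and fits one robust line per row with RANSAC gated by a slope window.
    Includes classical baseline detectors (filtered Hough transform,
    sliding-window least squares, per-cluster least squares), a bounding
    box IOU evaluation protocol with accuracy, precision and recall, and
    a seeded synthetic crop-field generator with exact ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    png,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
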