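Package: DepthHerd
Title: Top-View Depth-Camera Cattle Detection, Tracking and Lameness
    Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for overhead time-of-flight depth video of
    dairy cattle walking a corridor. Reads frame-per-row depth CSV streams
    (132 x 176 rasters of camera-to-surface distance in metres), detects cow
    instances with a pluggable detector plus a reference depth-threshold
    detector, rejects human-sized noise regions by masked pixel-sum
    thresholding, associates detections across frames with a greedy
    intersection-over-union tracker, extracts per-column maximum
    backbone-height profiles from Gaussian-smoothed height fields, and
    classifies cows as lame or sound with random forest, k-nearest-neighbour
    and decision-tree models or a transparent 1.2 m height cutoff. Includes
    CLEAR-MOT style evaluation (detection accuracy and MOTA) and a seeded
    synthetic herd simulator that renders cow- and human-shaped height blobs
    with exact ground truth, so every stage is testable without farm data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    data.table,
    jsonlite,
    yaml,
    igraph,
    png,
    randomForest,
    rpart,
    class
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
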