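Package: perclos
Title: Landmark-Based Driver Fatigue Detection with PERCLOS Scoring
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects driver fatigue from per-frame facial landmark meshes
    (468 indexed points per frame, as produced by attention-mesh style
    extractors). Computes eye and mouth aspect ratios (EAR/MAR) from fixed
    keypoint indices, segments blink, sustained eye-closure and yawn episodes
    by run-length analysis, scores PERCLOS per unit cycle and issues a
    normal/fatigued verdict from the combined PERCLOS and consecutive-frame
    rule. Also provides complete-IoU (CIoU) bounding-box geometry and
    precision/recall/AP/mAP detection evaluation, a synthetic
    facial-kinematics generator with ground truth for end-to-end testing
    without video data, delimited-text readers and writers for every format,
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
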