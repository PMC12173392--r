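Package: skelfall
Title: Skeleton-Based Fall Detection from Pose Keypoint Streams
Version: 0.1.0
Authors@R: person("skelfall", "developers", role = c("aut", "cre"),
    email = "skelfall@example.org")
Description: Toolkit for fall detection from per-frame human skeletons.
    Takes 2-D COCO 17-keypoint tracks (as produced by any pose estimation
    backend), computes nine geometric pose features (center of mass plus
    seven joint and reference-line angles), classifies each frame's
    posture as standing or lying with a built-in RBF-kernel support
    vector machine (alternatives: decision tree, random forest, gradient
    boosting), and confirms falls with a configurable per-track temporal
    criterion engine (lying-duration in seconds or frames,
    standing-to-lying transition speed). Includes a synthetic articulated
    skeleton simulator so the whole pipeline is testable without video or
    a pretrained detector, plus JSON Lines / COCO keypoint readers and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
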