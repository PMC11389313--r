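Package: gaitfall
Title: Temporal Gait Analysis and Fall-Risk Classification from Pose Keypoints
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for video-derived temporal gait analysis in Timed-Up-and-Go
    (TUG) recordings and downstream fall-risk classification. Parses 26-keypoint
    (Halpe full-body) pose-estimation output, smooths heel and big-toe vertical
    trajectories with a Savitzky-Golay filter, detects heel-strike and toe-off
    events as constrained local maxima, locates and excludes the mid-walk
    turning window from the deepest heel-strike maxima, computes temporal gait
    features (stance, stride and step time, cadence), and reproduces a
    class-balanced classification protocol (SMOTE oversampling, z-score
    scaling, stratified 70:30 split, twelve-classifier suite with grid search
    and ablations). A synthetic TUG trajectory and feature-table generator with
    known ground truth makes every stage testable without video data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    e1071,
    rpart,
    randomForest,
    xgboost,
    nnet,
    class
Suggests:
    signal,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
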