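Package: harselect
Title: Classifier-Independent Feature Selection for Smartphone Activity Recognition
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: A tested pipeline for studying signal features for human activity
    recognition (HAR) from a waist-worn smartphone inertial measurement unit.
    Generates labelled synthetic accelerometer/gyroscope recordings for
    able-bodied, elderly and hemiparetic-stroke gait profiles; corrects device
    orientation with a quaternion-derived rotation matrix estimated from a
    standing calibration sample; segments signals into one-second windows with
    transition buffering and seven class-granularity levels; extracts 76
    time-domain features per window; selects classifier-independent feature
    subsets with Relief-F, correlation-based feature selection (CFS) and the
    fast correlation-based filter (FCBF); and evaluates subsets against the
    full feature set with participant-wise leave-one-out cross-validation,
    paired sign tests and Benjamini-Hochberg correction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    e1071,
    rpart,
    jsonlite,
    pracma
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
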