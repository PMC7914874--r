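Package: gaitfmg
Title: Gait Phase Detection from Muscle Deformation with Standing-Based Calibration
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects the stance and swing phases of walking from multi-channel
    muscle-deformation (force-myography-style) signals recorded by a shank-worn
    sensor band. The classifier is a logistic regression calibrated only from
    short static standing postures, with a probability adjustment gated by the
    shank's anterior angular velocity derived from the on-board quaternion and
    gyroscope. Includes quaternion-to-Euler kinematics, posture-to-phase
    Euclidean-distance analysis, sample-based accuracy and per-phase true
    positive rate evaluation with video-to-sensor label alignment, an
    RBF-kernel support vector machine baseline, and a synthetic gait generator
    that provides labeled ground truth for end-to-end testing without hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    e1071,
    jsonlite,
    optparse,
    withr
Suggests:
    testthat (>= 3.0.0),
    glmnet
Config/testthat/edition: 3
RoxygenNote: 7.3.3
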