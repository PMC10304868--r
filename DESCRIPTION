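Package: gaitfrail
Title: Gait-Waveform Predictors of Grip Strength and an Analog Frailty Risk Score
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for discovering hand-grip-strength (HGS) predictors in
    in-shoe motion-sensor gait waveforms and for turning the resulting
    estimates into an analog frailty risk score.  The pipeline covers
    seeded synthetic cohort generation with planted waveform effects,
    stride segmentation and gait-cycle normalization of 9-channel foot
    motion signals, statistical parametric mapping (SPM) over the gait
    cycle with random-field-theory thresholds and Sidak-corrected post
    hoc tests, leave-one-subject-out LASSO (LOSO-LASSO) feature
    selection with label-matrix aggregation, agreement statistics
    (two-way random-effects ICC, Bland-Altman limits of agreement with
    confidence bounds, probability-based success-rate bounds), and
    cumulative-normal performance scores for grip strength and gait
    speed based on Asian population norms.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    glmnet,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
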