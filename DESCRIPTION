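Package: smartgait
Title: Gait-Pattern Classification from Smart-Shoe Pressure and Inertial Sensors
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: A tested pipeline for classifying normal and abnormal gait patterns
    (unstable left, unstable right, supination/toe-out, pronation/toe-in) from
    20-channel smart-shoe recordings: four plantar pressure sensors plus a
    three-axis accelerometer and gyroscope per shoe. Provides a seeded synthetic
    cohort generator with ground-truth gait events, pressure-threshold gait-event
    detection, segmentation under seven gait-cycle schemes (stride, step, stance,
    swing, single and double limb support), a canonical 224-column statistical
    feature battery with the 172-feature retention rule, information-gain feature
    ranking, standardization plus PCA with a cumulative explained-variance
    threshold, leave-one-participant-out evaluation of SVM, random forest, kNN
    and multinomial logistic classifiers with weighted multiclass metrics and
    column-wise confusion-matrix error rates, and benchmark drivers for
    sensor-combination ablation, principal-component sweeps, segmentation-scheme
    sweeps and paired one-tailed t-tests.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    e1071,
    ranger,
    class,
    nnet,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
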