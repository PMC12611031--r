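Package: msecg
Title: Metabolic Syndrome Detection from Multi-Lead ECG Signals
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A tested pipeline for automatic detection of metabolic syndrome
    from multi-lead electrocardiogram recordings. Provides a seeded synthetic
    ECG cohort generator with beat-level ground truth, Pan-Tompkins R-peak
    detection with derivative-inversion S-wave delineation and a time-flip
    (signal mirroring) variant for Q waves, a 30-item feature set built from
    QRS intervals, amplitude ratios and the frontal-plane cardiac axis on
    leads I and aVF, three classifier back-ends (RBF-kernel support vector
    machine, RobustBoost over tree learners, and a small two-stage
    convolutional neural network on raw windowed signals), subject-wise
    k-fold cross-validation with confusion-matrix metrics, and a statistical
    battery (Kolmogorov-Smirnov normality screen, Mann-Whitney group tests,
    point-biserial correlation, PCA loading-based feature relevance, and
    Bland-Altman agreement for detector validation).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    jsonlite,
    rpart,
    signal,
    stats,
    utils,
    yaml
Suggests:
    nortest,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
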