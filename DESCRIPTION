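Package: scapsta
Title: Quantifying Scapular Soft-Tissue Artifact from Two-Pose Landmark Data
Version: 0.1.0
Authors@R:
    person("Scapsta", "Developers", email = "scapsta@example.org", role = c("aut", "cre"))
Description: Tools to quantify the soft-tissue artifact (STA) of scapular
    skin markers from three-dimensional bony-landmark and marker-center
    coordinates acquired in two static arm postures (reference and
    elevated). Builds the International Society of Biomechanics (ISB)
    anatomical coordinate systems of the thorax, humerus and scapula from
    landmarks, expresses skin-marker displacement in the bone-fixed
    scapular frame, compares bone-based against marker-based
    scapulothoracic Euler angles (Y-X-Z) and humerothoracic elevation
    (Y-X-Y), and runs the cohort statistics: normality-gated descriptives,
    Friedman and Wilcoxon signed-rank tests with Bonferroni adjustment,
    paired t-tests, Spearman rank correlations, and Shrout-Fleiss
    intraclass correlation coefficients. A synthetic-cohort generator
    with planted kinematics and planted STA makes every pipeline stage
    testable without access to the original imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
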