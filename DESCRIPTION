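Package: nearfall
Title: Near-Fall Detection from Trunk Angular Kinematics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Automated detection and classification of near-fall events
    (balance recovery responses to trips, slips and antero-posterior loss of
    balance) from trunk angular kinematics measured by a wearable
    four-package inertial measurement cluster (IMC) or a single inertial
    measurement unit (IMU). Provides the algebraic cluster solver for the
    trunk angular acceleration vector, numerical-differentiation baselines,
    signal-analysis subroutines (autocorrelation, zero-crossing extrema
    segmentation, quartile and max-versus-mean outlier tests, an extrema
    distribution monitor), personalised threshold calibration from baseline
    walking, observation-window detection with onset/offset refinement, a
    three-step classifier separating balance recovery responses from
    activities of daily living, perturbation-type classification,
    classification performance metrics with prevalence extrapolation, and a
    seeded synthetic gait and perturbation generator for end-to-end testing.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
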