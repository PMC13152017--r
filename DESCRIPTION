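Package: kinfant
Title: Kinematic Feature Pipeline for Infant Movement Screening
Version: 0.1.0
Authors@R:
    person("kinfant", "maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: An open, preregistration-shaped pipeline for assessing infant
    cerebral-palsy risk from pose-estimated video. Ingests per-frame COCO-17
    keypoint detections, cleans and smooths the time series (confidence
    masking, linear interpolation, rolling median and mean filters),
    normalizes poses to a head-up torso-unit body frame, computes a
    preregistered 38-dimensional kinematic feature vector (joint angles,
    velocities, accelerations, entropy, bilateral cross-correlation), builds
    stratified train/validation/lock-box splits with hashed manifests, trains
    an imbalance-aware binary classifier of fidgety-movement status, and
    evaluates it threshold-free (ROC/PR curves, Youden's J operating points,
    permutation feature importance, power-law learning curves). A synthetic
    keypoint-cohort generator makes the whole pipeline testable without
    clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    glmnet,
    digest
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
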