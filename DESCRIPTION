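Package: reachkin
Title: Markerless Upper-Limb Reaching Kinematics from 2D Pose Landmarks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to turn 2D pose-landmark time series from markerless video
    tracking into upper-limb reaching kinematics. Reads block-structured
    landmark recordings (eight landmarks following the 33-point full-body pose
    convention), derives palm, paretic-shoulder and trunk effector
    trajectories, and computes bivariate variable error (BVE) and mean
    landmark speed per practice block. Aggregates per-block outcomes into
    group mean/SD tables and last-minus-first change scores, and fits linear
    mixed-effects models relating hand outcomes to proximal (shoulder, trunk)
    movement and motor impairment, with variance components, ICC and
    marginal/conditional R-squared. Includes a seeded synthetic reaching
    session generator with analytic ground truth for end-to-end validation,
    plus trajectory, BVE-bar and change-quadrant figures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    lme4,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
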