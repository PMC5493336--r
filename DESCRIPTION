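Package: phonegait
Title: Adaptive Gait and Visual Search Analysis for Walking-While-Phoning
    Obstacle Negotiation
Version: 0.1.0
Authors@R:
    person("Analysis", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Measurement-and-analysis pipeline for studies of obstacle
    negotiation under mobile-phone dual-tasking.  Computes fixation and
    area-of-interest visual-search metrics from mobile eye-tracker streams
    (dwell-threshold fixation detection, tracking-ratio screening,
    inter-rater ICC), adaptive-gait kinematics from 3-D marker trajectories
    around a surface height change (foot placement, stride length, vertical
    toe clearance, horizontal crossing velocity, head flexion, medial-lateral
    bivariate variable error), and the study-level statistics (one-way
    repeated-measures ANOVA with partial eta squared, Bonferroni pairwise
    comparisons, Levene and Kolmogorov-Smirnov assumption checks).  Includes
    a synthetic trial generator with known ground truth, readers and writers
    for canonical marker/gaze CSV files and C3D motion-capture exports, and
    report helpers reproducing condition-summary tables and percent-change
    arithmetic.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
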