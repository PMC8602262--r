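Package: boutloop
Title: Closed-Loop Optomotor Behavior Simulation and Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how larval zebrafish control swimming during
    the optomotor response under experimentally perturbed visual reafference.
    Provides a virtual closed-loop assay (vigor computation, velocity
    calibration, online bout detection, gain/lag/gain-drop reafference
    transformations and the standard trial protocols), a delayed
    feedback-controller model of bout generation with a genetic-algorithm
    fitting routine, offline behavioral analysis (flick-based bout
    segmentation, bout-power profiles, block-of-ten adaptation metrics and
    rank tests), calcium-imaging trace analysis (detrending, triggered
    averages, shuffle-null sensory/motor scores, leaky-integrator time
    constants, correlation-map ROI segmentation and bootstrap ternary
    response barcodes), and seeded synthetic-data generators so that every
    stage of the pipeline can be exercised and validated without recorded
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    graphics,
    jsonlite,
    signal,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    pracma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
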