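Package: spinegap
Title: Longitudinal Synaptic Structure Dynamics and the Closed-Loop
    Gap-Cross Assay
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying the turnover and stability of dendritic
    spines and axonal boutons followed across repeated in vivo imaging
    sessions, and for simulating and analyzing a whisker-dependent
    gap-crossing task run by a closed-loop controller. Includes a
    two-population (persistent/transient) kinetic simulator for spine and
    bouton cohorts, brightness-ratio hysteresis scoring of boutons,
    dual-scorer reconciliation, per-interval turnover and survival-fraction
    metrics with rank-sum group comparisons, cortical depth-profile
    normalization, and an adaptive Gaussian staircase session controller
    with sensor-event trial segmentation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
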