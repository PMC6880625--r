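Package: sstmouse
Title: Mouse-Tracking Stop-Signal Task Simulation and Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for simulating and analysing mouse-tracking variants of the
    stop-signal task. Simulates sessions under an independent horse-race model
    of going and stopping, with continuous cursor trajectories driven by
    participant-level impulsivity and inattention traits; computes trajectory
    kinematics (total distance, maximum velocity and acceleration, stopping
    distance) and integration-method stop-signal reaction time (SSRT) under
    preset and staircase stop-signal delays; and reproduces the downstream
    association and prediction analyses (Spearman correlation with
    Benjamini-Hochberg false-discovery-rate control, two-sample
    Kolmogorov-Smirnov comparisons, and ridge regression evaluated by 10-fold
    cross-validation nested in bootstrapped 5-fold cross-validation).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
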