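Package: bstask
Title: 1-Back Stroop High-Workload Task Engine and Mental-Fatigue Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Headless, testable implementation of a dual-task high-mental-workload
    paradigm combining a spatial 1-back task with a colour-word Stroop task.
    Provides constrained pseudo-random trial generation, time-pressure
    calibration from unconstrained reaction times (available time = 1.25 x
    mean required time), virtual-clock session execution (blocked workload
    comparison, 30-minute time-on-task fatigue induction, psychomotor
    vigilance test), stochastic simulated participants for desk-scale
    exercise, and the accompanying repeated-measures analysis pipeline
    (NASA-TLX scoring, block-wise behavioural metrics, normality-routed
    paired tests, Greenhouse-Geisser corrected RM-ANOVA, Friedman tests with
    Kendall's W, Spearman correlation matrices).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    car,
    nortest,
    withr,
    optparse
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
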