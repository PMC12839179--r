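Package: exosweep
Title: Parametric Stiffness and Timing Optimization of a Passive Ankle
    Exoskeleton
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale simulation pipeline for optimizing the spring
    stiffness and actuation timing of a passive ankle exoskeleton during
    the stance phase of walking.  Generates synthetic stance-phase gait
    trials (sagittal joint angles and net moments), models a tension-only
    spring actuator whose actuation timing is realized as a resting
    length via attachment-point trigonometry, distributes required joint
    moments across a Hill-type muscle set by static optimization, scores
    each condition with an Umberger-style muscle metabolic energy model,
    sweeps a stiffness-by-timing grid to map percent changes in energy
    expenditure relative to unassisted walking, and compares conditions
    with one-way ANOVA and Tukey post hoc tests.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
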