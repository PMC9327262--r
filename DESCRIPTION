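Package: rapidmotor
Title: Simulation and Analysis of Rapid Motor Behaviour Tasks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for studying rapid motor behaviour in bimanual
    object-interception tasks of the Object-Hit family, as run on robotic
    exoskeleton platforms. Provides a capacity-limited participant simulator
    that generates full trials (200 Hz bimanual kinematics plus object event
    logs) and whole cohorts with configurable age and sex effects; extraction
    of the standard battery of per-trial performance parameters, including a
    steady-state hit-rate detector built on an iterated Kolmogorov-Zurbenko
    moving-average filter; movement-strategy summaries (paddle-velocity cosine
    similarity and an inter-contact gap prediction model); and the cohort-level
    statistical layer: per-parameter age regressions, sex-difference t-tests,
    regression-slope comparison Z-tests, Bonferroni correction, normative
    standardisation and task scores, and effect-size projections.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
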