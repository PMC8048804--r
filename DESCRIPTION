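Package: equigait
Title: Treadmill Gait Analysis of Equine Forelimb Lameness
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantitative gait analysis of horses walking and trotting on an
    instrumented treadmill, centred on adaptation to forelimb lameness.
    Provides gait-event detection from vertical ground reaction force traces
    (slope-intersection hoof-on/off timing), per-stride temporal, kinetic and
    kinematic parameters, upper-body vertical movement symmetry indices
    (MinDiff, RUD, RDD, ROMz), centre-of-force dynamics relative to a trunk
    centre-of-mass proxy, per-horse Youden-index sensitivity/specificity
    tables, and linear mixed-model baseline-versus-lame comparison with
    Bonferroni correction. A synthetic trial generator emulates treadmill
    recordings (512 Hz forces, 256 Hz optical motion capture) with
    configurable lameness effect profiles and known ground-truth events, so
    the whole pipeline is testable without access to raw recordings.
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
    lmerTest,
    readr,
    rlang,
    signal,
    stats,
    tibble
Suggests:
    emmeans,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
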