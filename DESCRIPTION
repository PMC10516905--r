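Package: trancehrv
Title: Cardio-Respiratory Variability Analysis and Condition Decoding for
    Trance-State Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end analysis of autonomic cardio-respiratory signals
    recorded during self-induced cognitive trance, imagination and rest.
    Provides ECG preprocessing and R-peak detection, RR-interval artifact
    correction, time-domain, Welch spectral and approximate-entropy heart
    rate variability metrics with heart-rate (mean-RR) correction of
    spectral power, respiration-belt breath detection with rate, amplitude,
    inspiratory/expiratory phase-duration ratio and breath-to-breath
    variability metrics, phasic (task-minus-rest) versus tonic vagal
    analysis, and per-feature linear-discriminant decoding of conditions
    under leave-one-subject-out cross-validation with permutation
    maximum-statistics familywise inference. A synthetic cohort generator
    with known ground truth (beat and breath times, injected condition
    effects) makes every stage testable without human recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    jsonlite,
    stats,
    utils
Suggests:
    MASS,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
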