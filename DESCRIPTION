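Package: keytap
Title: Kinetic Scoring and Evaluation of Keyboard Finger-Tapping Tests
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Offline scoring and evaluation of web-based keyboard tapping
    tests used to quantify distal and proximal upper-limb bradykinesia in
    Parkinson's disease. Computes the three kinetic parameters of the
    Distal Finger Tapping (DFT, 20 s) and BRAIN (30 s) tests -- kinesia
    score (tap count), akinesia time (mean key dwell time) and
    incoordination score (variance of travelling time between taps) --
    from raw keystroke press/release streams, and provides the full
    evaluation battery around them: normality-gated two-group comparisons,
    empirical ROC analysis with DeLong confidence intervals, sensitivity
    at fixed specificity, logistic-regression combination of parameters,
    clinical-score correlation, test-retest reliability (ICC and
    repeated-measures ANOVA), and mixed-effects modelling of On/Off motor
    fluctuations. A seeded hierarchical simulator generates keystroke
    cohorts whose scores match configurable group distributions, so every
    analysis stage is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    lme4,
    stats,
    tools,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
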