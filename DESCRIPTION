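Package: efmt
Title: Adaptive Emotional N-Back Training and In-Silico Randomized Trial
    Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Implements an adaptive dual N-back cognitive-emotional training
    task (emotion-labelled face stimuli, with a matched neutral-shape control
    task), simulated participants with configurable psychometric and clinical
    trajectory models, permuted-block randomization, a full in-silico
    randomized controlled trial pipeline with protocol adherence and
    discontinuation rules, and the trial's statistical analysis suite:
    mixed-model repeated measures (MMRM) with unstructured within-subject
    covariance and weekly least-squares-mean contrasts, LOCF sensitivity
    analysis, responder, dose-response, and symptom-item-level analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    tools,
    utils,
    nlme,
    MASS,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
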