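Package: tnsalvage
Title: Chrono-Stratified Survival, Latent Subtyping and Cost-Utility
    Modelling for Salvage Therapy in Recurrent Trigeminal Neuralgia
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing salvage-therapy outcomes in recurrent
    trigeminal neuralgia after failed microvascular decompression. Provides
    a calibrated synthetic cohort generator with piecewise-exponential
    recurrence hazards and class-structured biomarkers; from-scratch
    Kaplan-Meier estimation with Greenwood variance, log-rank tests and Cox
    partial-likelihood fitting with Efron ties, including an epoch-split
    (time-varying effect) analysis at a 24-month cutpoint; latent class
    analysis of binary clinical indicators by expectation-maximisation with
    BIC model selection; a two-arm Markov cohort cost-utility engine with
    transition and value calibration, ICER/dominance logic, one-way and
    probabilistic sensitivity analysis; and a reproducible pipeline with
    simplified multiple imputation and Rubin pooling.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    survival
Config/testthat/edition: 3
RoxygenNote: 7.3.3
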