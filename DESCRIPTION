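Package: predinf
Title: Predictive-Inference Change-Point Task Simulation and Metacognition Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the circular predictive-inference ("particle catching")
    change-point task, runs the reduced quasi-optimal Bayesian change-point
    learner over outcome streams, generates synthetic participant cohorts whose
    actions and confidence reports are modulated by three correlated
    transdiagnostic symptom dimensions (anxious-depression, compulsive
    behaviour and intrusive thought, social withdrawal), derives trial-level
    behaviour metrics with the standard learning-rate exclusions, and fits the
    mixed-effects analyses of action-confidence coupling and of the influence
    of model-derived evidence on confidence and action, with subject-clustered
    heteroskedasticity-consistent standard errors, White's test, and
    Bonferroni correction over psychiatric moderators. Questionnaire item
    tables can be scored into the three transdiagnostic dimensions via an
    external factor weight matrix.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    lme4,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    sandwich,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
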