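Package: vltraj
Title: Hierarchical Bayesian Analysis of Resistance-Training Volume-Load
    Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how training volume-load (load x sets x
    repetitions) evolves across resistance-training sessions in clinical
    cohorts, and how that evolution varies between exercises and between
    individuals. Provides construction of the baseline-standardized
    volume-load outcome from raw training logs (familiarization removal,
    session-validity filtering, repetition-overshoot equalization,
    per-exercise z-standardization), a three-level hierarchical Bayesian
    quadratic growth model with intercept, linear and quadratic components
    varying by exercise, patient and patient-by-exercise (fitted by Gibbs
    sampling via 'rjags'), posterior-derived quantities (heterogeneity
    intervals, coefficients of variation, variance ratios, Monte-Carlo
    plateau-timing distributions, responder classification,
    within-individual variability), leave-one-out model comparison via
    Pareto-smoothed importance sampling, load-progression planners, and a
    seeded synthetic-cohort generator for end-to-end testing and parameter
    recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
Depends: R (>= 4.1)
Imports:
    rjags,
    coda,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    yaml,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
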