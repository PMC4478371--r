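Package: melcea
Title: Cost-Effectiveness Modelling of Targeted Therapy in Metastatic Melanoma
Version: 1.0.0
Authors@R:
    person("Alex", "Morgan", email = "alex.morgan@example.org", role = c("aut", "cre"))
Description: A three-state (stable disease, progression, death) monthly-cycle
    cohort model for cost-effectiveness analysis of oncology treatment
    strategies, built in the partitioned-survival style: state occupancy is
    derived directly from overall-survival and progression-free-survival
    curves, which are extended to a lifetime horizon with the declining
    exponential approximation of life expectancy (DEALE). The package
    accumulates drug, toxicity-management and treatment-crossover costs and
    quality-adjusted life years over the cohort trace, builds the
    incremental cost-effectiveness frontier with strict and extended
    dominance, and runs deterministic (one-way) and probabilistic
    (Monte Carlo, beta/gamma) sensitivity analyses including
    cost-effectiveness acceptability curves. Ships a fully parameterized
    metastatic-melanoma scenario (dacarbazine versus the BRAF inhibitors
    dabrafenib and vemurafenib, 2013 USD) and a generator of trial-like
    synthetic survival curves so every stage is testable without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
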