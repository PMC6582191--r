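Package: kinfit
Title: Global, Multi-Objective, and Bayesian Calibration of Unstructured
    Microbial Growth Kinetics
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Sequential three-stage calibration of unstructured kinetic
    models (Monod, Moser, and related growth laws coupled to substrate
    depletion ordinary differential equations) against sparse, noisy,
    two-variable batch biodegradation time series.  Stage one is a
    self-adaptive differential evolution global search locating the best
    compromise solution and the per-variable extreme solutions; stage two
    evolves the Pareto front of per-variable fitting errors with an
    elitist non-dominated sorting genetic algorithm and selects the best
    compromise member; stage three is a multi-chain approximate Bayesian
    computation sampler with differential-evolution proposals that
    targets the compromise summary statistics, monitored with the
    Gelman-Rubin statistic and summarized as 95% parameter and predictive
    uncertainty bands.  Includes a registry of eight growth laws, a
    synthetic batch-experiment generator, residual diagnostics, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
NeedsCompilation: yes
Depends: R (>= 4.1)
Imports:
    deSolve,
    e1071,
    jsonlite,
    nortest,
    rlang,
    stats,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
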