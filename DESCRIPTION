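Package: dynesm
Title: Two-Level Dynamic Structural Equation Models for Experience-Sampling Data
Version: 0.1.0
Authors@R:
    person("dynesm", "developers", email = "dynesm@example.org", role = c("aut", "cre"))
Description: Tools for analysing intensive longitudinal (experience sampling /
    ecological momentary assessment) data with two-level dynamic structural
    equation models: a bivariate lag-1 within-person process with
    person-specific latent means, autoregressive and cross-lagged
    coefficients, and log-scale random residual variances; between-person
    regressions of these dynamic parameters on baseline traits and
    sociodemographic covariates; distal follow-up outcomes; and indirect
    (a x b) effects computed from posterior draws. Estimation is by Markov
    chain Monte Carlo (conjugate Gibbs updates with random-walk Metropolis
    steps for the log-variance random effects), with multi-chain management,
    thinning, and split-chain potential scale reduction diagnostics. A
    synthetic study generator emulates a full ESM design (prompt schedules,
    partial compliance, within-person dynamics, between-person structure,
    follow-up outcomes) so the entire pipeline can be exercised without
    external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0),
    mvtnorm,
    coda
Config/testthat/edition: 3
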