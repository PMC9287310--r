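Package: hybridctrl
Title: Hybrid-Control Arm Construction and Dynamic Borrowing for Early-Phase Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds an external-control cohort from a completed trial's control
    arm and combines it with the randomized control arm of a small concurrent
    trial.  Covers eligibility filtering with attrition reporting, endpoint
    harmonization across differing tumour-assessment schedules (disease control
    at 12 weeks, survival truncation), propensity-score estimation with
    standardized-mortality-ratio weighting and standardized-mean-difference
    balance diagnostics, frequentist weighted effect estimation (logistic,
    Cox, Kaplan-Meier with robust variance), Bayesian dynamic borrowing with
    commensurate priors (Bernoulli-logit and Weibull survival models fitted by
    MCMC), a two-trial synthetic data generator, and a simulation harness for
    comparing static and dynamic borrowing operating characteristics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    survival,
    sandwich,
    rjags,
    coda,
    yaml,
    jsonlite,
    MASS
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
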