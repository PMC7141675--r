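Package: necbench
Title: Benchmarking Threshold Estimators for Binomial Survival
    Dose-Response Data
Version: 0.1.0
Authors@R:
    person("Marine", "Ecotox Stats Group", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Monte Carlo comparison of no-effect-concentration (NEC)
    threshold estimators for binomial survival dose-response experiments.
    Simulates survival datasets from threshold (NEC) and non-threshold
    (three-parameter log-logistic) curves under categorical and continuous
    experimental designs, fits four estimators (log-logistic ECx by maximum
    likelihood, NEC by maximum likelihood, Bayesian NEC by adaptive
    Metropolis-within-Gibbs MCMC, and bias-reduced piecewise logistic
    regression with a single breakpoint), and evaluates accuracy (RMSE,
    highest density intervals) together with true and spurious
    threshold-model selection rates under AIC, AICc and DIC weights.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    RcppArmadillo,
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
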