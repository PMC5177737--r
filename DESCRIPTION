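Package: hemopk
Title: Population Pharmacokinetics and Bayesian Forecasting for Clotting Factor Concentrates
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A self-contained population-pharmacokinetics engine for factor
    VIII and factor IX concentrates used in hemophilia prophylaxis. Reads and
    validates concentration-time datasets in the NONMEM-dialect CSV layout,
    evaluates closed-form 1-, 2- and 3-compartment intravenous infusion
    models, fits hierarchical nonlinear mixed-effects models by a
    Laplace/FOCE-with-interaction approximation with M3 censored likelihood
    for below-quantification observations, builds covariate models stepwise
    by likelihood ratio, evaluates models by diagnostics, bootstrap and
    cross-validation, and produces Bayesian individual forecasts with 95%
    credibility bands and times to clinically relevant factor thresholds.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    jsonlite,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
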