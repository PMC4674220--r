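Package: deerforecast
Title: Bayesian State-Space Forecasting of White-Tailed Deer Management
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Fits a Bayesian hierarchical state-space model of white-tailed
    deer population dynamics in a network of parks: a stage-structured
    Lefkovitch projection with density-dependent fecundity and lognormal
    process error, linked to distance-sampling density estimates and
    age/sex classification counts. Provides an adaptive
    Metropolis-within-Gibbs sampler, posterior predictive model checking,
    eigenanalysis of posterior projection matrices, five-year forecasting,
    and evaluation of culling, sterilization and contraception regimes via
    probability-of-objective and net-effect decision metrics, together with
    a synthetic-data generator that reproduces the survey structure.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
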