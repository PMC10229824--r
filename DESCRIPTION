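Package: erpdcm
Title: Dynamic Causal Modelling of Two-Region Evoked Responses
Version: 0.1.0
Authors@R:
    person("M.", "Keller", email = "mkeller@example.org", role = c("aut", "cre"))
Description: Generative neural-mass modelling and Bayesian system
    identification for event-related potentials recorded simultaneously from
    two reciprocally connected brain regions. Provides alpha-kernel
    convolution dynamics with sigmoid firing-rate coupling, variational
    Laplace inversion of competing connectivity architectures, fixed- and
    random-effects Bayesian model selection with exceedance probabilities,
    and a parametric empirical Bayes second level (with Bayesian model
    reduction) relating connection strengths to behavioural covariates.
    Includes LFP preprocessing (decimation, zero-phase band-pass, event-locked
    epoch averaging) and a synthetic-cohort generator with known ground truth
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
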