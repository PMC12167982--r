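Package: twinmodels
Title: Heterogeneity and Reinforcement Twin Models for Longitudinal Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Generative models for longitudinal panel and event-history data
    that come in statistically indistinguishable "twin" pairs: a latent-trait
    (heterogeneity) model and a reinforcement model with identical joint
    distributions over whole trajectories.  Implements the Polya urn and its
    uniform-p Bernoulli twin, the Gaussian latent-factor (Q-)model and its
    sequential-update twin, and a Gamma-frailty pure-birth contact process
    with its self-exciting point-process twin, each with exact simulators and
    log-likelihoods, parameter maps linking the pairs, hybrid mixtures, a
    model-equivalence checking suite, and a permutation runs test of
    exchangeability for panel data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    parallel,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
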