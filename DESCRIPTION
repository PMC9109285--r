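Package: auditbi
Title: Bayesian Reanalysis of Cluster-Randomized Brief-Intervention Alcohol Trials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to reanalyze two-arm brief-intervention trials for risky
    alcohol use (AUDIT screening) in the Bayesian framework. Provides
    hierarchical Bernoulli-logit and Gaussian outcome models with health-center
    random intercepts, an exact log-posterior with analytic gradients, a
    Hamiltonian Monte Carlo sampler with dual-averaging step-size adaptation
    and split-R-hat/bulk-ESS diagnostics, decision-oriented posterior
    summaries (cumulative effect-size probability tables, posterior densities),
    a maximum-likelihood mixed-effects comparison fit, and a synthetic-trial
    generator emulating the design of a five-center trial of a health
    technician delivered brief intervention.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    lme4,
    jsonlite,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
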