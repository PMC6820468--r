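Package: galadhmm
Title: Continuous-Time Hidden Markov Modelling of Longitudinal Biomarker
    Surveillance for Hepatocellular Carcinoma
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for prospective cancer surveillance from irregularly
    sampled longitudinal serum-biomarker scores (such as the GALAD score
    used in hepatocellular carcinoma screening).  Implements an absorbing
    two-state continuous-time hidden Markov model in which tumour onset is
    a latent change-point after which the mean biomarker trajectory rises
    linearly in a responder sub-population, onset hazard is log-linear in a
    patient-specific baseline random effect, and clinical diagnosis lags
    onset through a constant hazard with no false positives.  Provides a
    synthetic-cohort simulator matching the generative model, Bayesian
    data-augmentation Markov chain Monte Carlo inference with convergence
    diagnostics, per-visit posterior predictive probabilities of
    undiagnosed tumour presence under moment-matched informative priors,
    and longitudinal screening evaluation (per-patient and per-observation
    specificity, sensitivity, timeliness, ROC/AUROC) including a
    fixed-threshold comparator.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    pracma,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
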