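Package: reactfc
Title: Molecular-Enriched Functional Connectivity Analysis with Receptor
    Density Templates
Version: 0.1.0
Authors@R:
    person("reactfc", "developers", email = "reactfc@example.org",
           role = c("aut", "cre"))
Description: Two-step dual-regression estimation of neurotransmission-enriched
    functional connectivity from resting-state BOLD series and PET/SPECT-derived
    molecular density templates, with nonparametric max-cluster-size
    family-wise-error group inference (Freedman-Lane permutation of nuisance
    covariates), analgesic responder classification, and frequentist plus
    Bayesian (JZS / stretched-beta prior) treatment-response statistics. Ships a
    seeded synthetic-data generator that emulates the full data structure of a
    chronic-pain pharmaco-fMRI cohort so the whole pipeline is testable against
    known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
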