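Package: sealIH
Title: Latent Individual Heterogeneity in Reproductive Rates from
    Multistate Encounter Histories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting and characterizing latent individual
    heterogeneity (frailty) in reproductive rates from multistate
    encounter histories of long-lived vertebrates, built around the
    Erebus Bay Weddell seal study system. Encounter histories record a
    female's yearly reproductive state (first-time breeder, experienced
    breeder, skip-breeder) from recruitment to last sighting. The package
    provides the encounter-history data model and per-individual
    trajectory statistics; a synthetic-population generator with the same
    statistical structure; three competing hierarchical Bayesian
    logistic models of breeding probability (no heterogeneity, fixed
    heterogeneity, environment-dependent heterogeneity) fitted by a
    compiled adaptive Metropolis-within-Gibbs sampler; posterior
    predictive checks built on bespoke trajectory discrepancy
    statistics; and projections of expected reproductive output for
    hypothetical frail, average, and robust females.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    coda,
    rjags,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
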