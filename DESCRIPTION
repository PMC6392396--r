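Package: pollisize
Title: Allometric Body Size Estimation for Bees and Hoverflies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates pollinator body size (dry weight, mg) from the
    intertegular distance (ITD, mm) using hierarchical Bayesian ln-ln
    power-law models with sex and taxonomic co-variates and nested
    region/species random intercepts, including a phylogenetically
    constrained variant. Provides specimen-table quality control (pin-weight
    correction, introduced-range exclusions), a registry of published
    allometric conversions (foraging distance, tongue length, wing loading,
    nectar load), phylogenetic tools (polytomy grafting onto a genus
    backbone, penalized-likelihood chronograms, Pagel's lambda), model
    selection by Bayesian R-squared and species-grouped K-fold
    cross-validation, intraspecific OLS diagnostics with sample-size
    adequacy resampling, and a synthetic-data generator with known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    coda,
    jsonlite,
    rjags,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    phangorn,
    phytools,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
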