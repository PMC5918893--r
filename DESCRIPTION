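Package: rarecomm
Title: Commonness and Rarity in Island Arthropod Assemblages
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Comparative community-structure analysis for species-level
    assemblage tables: Hill-number diversity profiles, first-order jackknife
    richness estimation and sampling completeness, maximum-likelihood fitting
    of species abundance distribution models (Fisher's logseries, the
    zero-truncated Poisson lognormal, and the gambin gamma-binomial model)
    with small-sample AICc model selection, occupancy frequency distributions
    with Tokeshi modality tests, and quartile-based screening of potentially
    rare species with expert-annotation triage into tourist, pseudo-rare
    microhabitat specialist, and truly rare categories.  Assemblages can be
    deconstructed by distributional status (endemic, native non-endemic,
    introduced).  Ships a worked dataset of epigean spiders and ground
    beetles sampled by pitfall transects in the laurel forests of Terceira
    (40 sites) and Madeira (47 sites), and a seeded community simulator for
    end-to-end validation of every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
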