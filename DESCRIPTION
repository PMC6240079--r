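Package: crossflux
Title: Harmonization and Synthesis of Cross-Ecosystem Carbon Flux Measurements
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to harmonize heterogeneous ecological carbon flux
    measurements into common areal carbon units (gC per m2 per year of the
    recipient ecosystem), derive decomposition fluxes from the exponential
    litter-decay model, close gross primary production / respiration / net
    ecosystem production identities, and compute the grouped summaries and
    heterotrophy statistics used in meta-ecosystem syntheses of
    cross-ecosystem subsidies. Includes shoreline-geometry re-expression of
    lateral aquatic-to-terrestrial flows, a fully seeded synthetic-data
    generator with known ground truth for validating every harmonization
    path, and a reproducible end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    digest,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
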