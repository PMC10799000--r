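Package: dryq10
Title: Partitioning and Temperature Sensitivity of Soil Organic and Inorganic
    Carbon CO2 Emissions in Drylands
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to partition soil incubation CO2 effluxes into soil organic
    carbon (SOC) and soil inorganic carbon (SIC) derived components with a
    two-end-member delta13C mixing model, fit exponential temperature
    responses (Q10), analyse Q10 variation along an aridity gradient
    (regressions, paired moisture-treatment tests, factor correlations),
    run a PCA-composite path analysis with standardized effect
    decomposition, and carry out the dryland carbon upscaling arithmetic.
    Includes a seeded synthetic-cohort generator with known ground truth so
    the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    readr,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
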