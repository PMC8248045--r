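Package: ecosunpass
Title: Environmental Hazard Scoring and Ecofriendliness Ranking of Sunscreen UV Filters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores the environmental hazard of individual sunscreen UV filters
    across six environmental chapters (biodegradation, bioaccumulation, acute and
    chronic aquatic toxicity, sediment and terrestrial toxicity), applies
    regulatory cut-off criteria (endocrine disruption, PBT/vPvB, acute and
    chronic aquatic toxicity thresholds), aggregates per-substance scores over a
    formulation into a concentration-weighted ecorank and percent
    ecofriendliness, and combines the result with simulated UV efficacy (SPF and
    UVA-PF from a step-film transmission model) into a single ecofriendliness
    value with a pass/fail threshold. Includes a synthetic dossier and spectrum
    generator for method evaluation, CSV/YAML input and output, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    pracma,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
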