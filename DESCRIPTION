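Package: shorepop
Title: Within-Site Demography of Intertidal Mussel Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for within-site analysis of rocky-shore mussel populations
    from quadrat surveys: seasonally oscillating von Bertalanffy growth
    inferred from length-frequency data with an ELEFAN-style restructuring
    and genetic-algorithm fit, catch-curve mortality from length-derived age
    structure, cover-standardized density and biomass, a basal-area crowding
    index for monolayer aggregations, recruit classification, tidal immersion
    modelling from hourly tide-gauge series, and potential reproductive
    output. Includes an individual-based population generator with known
    ground truth for validation, and an end-to-end pipeline that turns raw
    survey tables into per-shore and per-quadrat summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    minpack.lm
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
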