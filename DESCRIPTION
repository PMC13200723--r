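Package: sdaflux
Title: Post-Prandial Energetics and Nitrogen Budget Analysis for Small Fish
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for whole-animal digestive energetics in small
    aquatic animals: converts intermittent-flow respirometry oxygen traces into
    per-cycle oxygen consumption rates, estimates standard metabolic rate and the
    specific dynamic action response (magnitude, duration, net peak) with
    quality-control and exclusion rules; computes static-chamber net fluxes of
    total ammonia and titratable alkalinity, net acid-base exchange, cumulative
    ammonia budgets and ammonia speciation; models the oxygen cost of gastric
    acid secretion; provides growth-trial arithmetic (specific growth rate, feed
    conversion ratio, condition factor) and relative gene expression by the
    2^-ddCt method with multi-reference normalization. A seeded synthetic-data
    generator emulates every input for parameter-recovery testing.
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
    car,
    emmeans
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
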