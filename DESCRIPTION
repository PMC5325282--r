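Package: eagledemog
Title: Demographic Analysis of Territorial Raptor Populations Under
    Anthropogenic Mortality
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for quantifying the population-level cost of
    human-related mortality in long-lived territorial raptors such as the
    golden eagle (Aquila chrysaetos).  Implements known-fate
    radio-telemetry survival estimation with staggered entry, censoring
    and AICc model selection; fecundity and fledgling sex-ratio
    statistics; a five-stage post-breeding-pulse matrix model for the
    potential population growth rate with delta-method variance; the
    floater-to-breeder ratio at Moffat's equilibrium; a replacement-chain
    model of the demographic cost of a single fatality scaled to annual
    mortality tolls; and an individual-based stochastic simulator of a
    territorial population with floaters that generates the telemetry and
    nest-survey tables the estimators consume.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
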