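Package: phenocurrency
Title: Currency-Dependent Resource Phenology and Trophic Mismatch
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for quantifying how the currency used to measure resource
    phenology (specimen abundance versus community biomass) changes inferences
    about consumer-resource synchrony. Reconstructs daily arthropod biomass
    series from interval-based pitfall-trap counts via taxon-specific
    length-mass allometry, computes cumulative-threshold (50%) phenology dates
    by linear interpolation, estimates shorebird hatch dates from chick mass
    through a fitted logistic growth curve, fits linear mismatch trends with
    case-bootstrap percentile confidence intervals, and provides a conceptual
    simulator in which year-varying mass-per-specimen schedules generate
    currency-specific rates of phenological change. Includes a synthetic-data
    generator with analytic ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    mgcv,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
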