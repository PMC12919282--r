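Package: budwatch
Title: Birder-User-Day Count Models and Wetland Birdwatching Valuation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for modelling birdwatcher visitation at wetland sites from
    citizen-science checklist records.  Checklists are aggregated into monthly
    Birder User Days (BuDs) and species-richness series, joined with rainfall,
    temperature and wet-surface-area covariates (including linear gap filling
    across cloud-obscured months), and modelled with Poisson and negative
    binomial count regressions using Newey-West HAC standard errors, plus
    fixed-effects Poisson panel models with hotspot-clustered bootstrap
    inference.  Fitted coefficients feed scenario projections of visitation
    change under increased wet surface area (direct and richness-mediated
    chains) and activity-weighted birdwatching-expenditure estimates.  A
    synthetic-data generator with known ground-truth parameters stands in for
    restricted checklist and survey microdata so the whole chain is testable.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: stats, utils, graphics
Suggests: testthat (>= 3.0.0), sandwich, MASS, withr, jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
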