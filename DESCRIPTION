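Package: fluxlegacy
Title: Drought Legacy Effects on Forest Carbon Fluxes from Eddy Covariance Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis pipeline for quantifying drought legacy effects on
    ecosystem carbon fluxes measured by eddy covariance. Provides
    friction-velocity (u*) threshold detection with bootstrap uncertainty,
    marginal-distribution-sampling gap-filling, nighttime flux partitioning
    into gross primary productivity and ecosystem respiration via the
    Lloyd-Taylor model, Michaelis-Menten light-response fits, a daily
    standardized precipitation-evapotranspiration index (SPEI) at arbitrary
    aggregation scales, greenness-based phenology with double-logistic fits
    and curvature-based transition dates, day-of-year by timescale drought
    fingerprint correlations, and restricted-cubic-spline regression with
    Wald chi-square feature importance for detecting legacy effects through
    model comparison. A synthetic flux-tower generator with known ground
    truth makes every stage testable without tower data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    minpack.lm,
    stats,
    utils,
    zoo
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
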