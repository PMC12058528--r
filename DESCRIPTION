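Package: ulexp
Title: Unprecedented Lifetime Exposure to Climate Extremes Across Birth Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Projects the fraction of birth cohorts whose cumulative lifetime
    exposure to climate extremes (heatwaves, crop failures, droughts, river
    floods, wildfires, tropical cyclones) exceeds the 99.99th percentile of
    exposure expected in a stationary pre-industrial climate. Accumulates
    annual gridded exposure fractions over cohort lifetimes, bootstraps a
    pre-industrial null distribution per grid cell, resamples ensemble
    projections onto incrementally warming global mean temperature (GMT)
    pathways under a warming-level matching constraint, converts five-year
    demographic tables to annual grid-scale birth-cohort sizes, and
    stratifies emergence by population-weighted quantiles of socioeconomic
    vulnerability. Includes a synthetic-data generator with analytic ground
    truth so the full pipeline is testable without external archives.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
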