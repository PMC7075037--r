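Package: ejburden
Title: Risk-Based Coronary Heart Disease Burden and Environmental Justice
    Disparity Analysis for Traffic-Related Air Pollutants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Apportions county-level coronary heart disease (CHD) burden
    attributable to traffic-related air pollutants (black carbon, nitrogen
    dioxide) across census tracts using a risk-based model: county crude
    rates are anchored at the population-midpoint exposure, scaled tract by
    tract with literature effect estimates, rebaselined against the lowest
    exposed tract, and multiplied by tract populations to give expected
    annual cases. Includes environmental-justice (EJ) tract classification
    from demographic fractions with American Community Survey style
    uncertainty handling, exposure-quartile disparity statistics (relative
    incidence ratios with Katz log-ratio confidence intervals, quartile
    demographic composition), raster-to-tract exposure aggregation, and a
    calibrated synthetic-county generator so the full pipeline runs and is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
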