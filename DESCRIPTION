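Package: woodytrends
Title: Hexagon-Grid Trend Analysis of Woody Vegetation from Satellite Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects directional change in woody vegetation cover (trees and
    shrubs) along tropical mountain elevation gradients from annual land-cover
    maps derived from 16-day satellite vegetation-index composites. Provides a
    fully truth-labeled synthetic landscape generator emulating 250 m
    composite time series with class-specific phenology, reliability flags and
    scripted land-cover transitions; multi-window temporal feature extraction;
    zone-specific Random Forest classification with accuracy assessment; a
    regular hexagon tessellation with zonal attributes; per-hexagon linear
    trend significance filtering with elevation-zone and country accounting;
    and exhaustive logistic model selection with Akaike weights relating
    forest gain and loss to topographic and socioeconomic covariates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ranger,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
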