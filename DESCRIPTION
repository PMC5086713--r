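Package: pm25gwr
Title: Real-Time Satellite-Derived PM2.5 Estimation by Geographically
    Weighted Regression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A reusable pipeline for estimating ground-level PM2.5 mass
    concentrations from satellite aerosol optical depth (AOD) at overpass
    time. Fuses Dark Target (3 km) and Deep Blue (10 km) AOD retrievals
    after quality-assurance filtering, applies physical corrections for
    boundary-layer height and hygroscopic growth, collocates station
    records across time zones, and fits per-day geographically weighted
    regression (GWR) models with adaptive bisquare bandwidths. Includes
    seasonal k-fold cross-validation diagnostics, seasonal surface
    aggregation with WHO interim-target exceedance, and a fully
    deterministic synthetic-scene generator so every stage is testable
    without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    graphics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    geosphere,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
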