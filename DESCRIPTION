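Package: migrniche
Title: Migration Phenology and Seasonal Climatic Niche Overlap from Satellite Telemetry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the full analysis chain used to study seasonal climatic
    niche switching in satellite-tracked migratory birds. Provides a seeded
    synthetic-data generator for Argos-like telemetry and seasonal climate
    grids; location-error filtering with a continuous-time correlated random
    walk (integrated Ornstein-Uhlenbeck velocity) state-space model fitted by
    Kalman-filter maximum likelihood; net-squared-displacement (NSD) migration
    phenology via single and double sigmoid (logistic) models with derived
    migration metrics and analytic timing segmentation; hourly movement speed
    and trip-distance summaries; and climatic niche overlap in the space of the
    first two environmental principal components using kernel-smoothed 100x100
    occupancy grids, Schoener's D and the Hellinger-based I statistic.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    geosphere,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    pracma,
    knitr
Config/testthat/edition: 3
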