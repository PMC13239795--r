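Package: pedrisk
Title: Pediatric Environmental Co-Exposure Risk Mapping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for mapping pediatric risk from co-exposure to extreme
    heat and air pollution. Counts daily exceedances of monthly climate
    normals and fixed pollutant thresholds on gridded fields, fits per-pixel
    linear trends, harmonizes rasters of different resolutions by Lanczos
    resampling, detects co-exposure hotspots with the Getis-Ord Gi* local
    statistic under k-nearest-neighbour spatial weights, constructs a
    tract-level pediatric vulnerability index by comparing dimensionality
    reduction methods (PCA, exploratory factor analysis with oblimin
    rotation, plus pluggable embedding adapters) with bootstrap confidence
    intervals for explained variance, and crosses collapsed hazard levels
    with vulnerability tertiles into a bivariate risk classification with
    rural-urban summaries. A seeded synthetic-data generator emulates the
    statistical structure of the gridded and tract-level inputs so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    Rtsne,
    uwot
Config/testthat/edition: 3
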