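Package: plasticmapr
Title: Mapping Agricultural Plastic Covers from Fused Optical and Radar Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An offline, testable pipeline for mapping plasticulture
    (plastic-mulched farmland and plastic covers above vegetation) from
    annual time series of co-registered optical and radar imagery.
    Provides a synthetic scene simulator with class-specific phenology,
    cloud cover and SAR speckle; cloud masking, speckle smoothing, sensor
    pairing and spectral index computation; two-branch feature extraction
    (annual aggregated statistics and the frequency of plastic detection);
    random-forest classification with minimum-mapping-unit sieving;
    point-based accuracy assessment with confusion matrices; and spatial
    quality control through a bare-soil index, hexagonal aggregation and
    per-hexagon regression diagnostics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    ranger,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    randomForest,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
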