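Package: basinrank
Title: Multi-Criteria Prioritization of River Basins for Nutrient Studies
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Ranks large candidate river basins for nutrient (nitrogen and
    phosphorus) water-quality studies using two complementary weighted
    percent-rank composites: an impact approach that prioritizes basins with
    the highest nutrient sources, stream and groundwater concentrations, and
    receptor exposure, and a variability approach that prioritizes basins
    whose subbasins span wide ranges in concentrations and driving factors,
    include low-concentration streams, and are poorly predicted by current
    watershed models. Includes percent-rank normalization with spreadsheet
    tie handling, interquartile-range aggregation of subbasin values,
    category-weighted scoring, a top-four water-quality eligibility penalty,
    regional and national ranking, priority-basin selection and comparison
    utilities, and a seeded synthetic roster generator for end-to-end
    testing without geospatial inputs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
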