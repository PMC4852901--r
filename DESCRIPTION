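Package: paleoprod
Title: Paleolimnological Production Trends, Sediment Chronologies and
    Atmospheric Nutrient Deposition Mapping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for reconstructing whole-lake primary production
    histories from dated sediment cores and relating them to industrial
    deposition gradients and climate.  Implements lead-210 constant
    rate of supply (CRS) chronologies with caesium-137 validation and
    constrained polynomial age-depth smoothing; inference of sedimentary
    chlorophyll-a from visible reflectance spectra via the 650-700 nm
    absorbance peak area; enrichment factors against pre-industrial
    baselines with dibenzothiophene (DBT) based site classification;
    continuous two-segment (breakpoint) regression with an F test;
    standardized production Z scores, 5-year binning and climate
    correlations; and ordinary kriging of snowpack nutrient loadings
    with radius-integrated deposition estimates.  A synthetic-data
    module generates cores, snow grids and climate series with the
    statistical structure the analysis assumes, so the whole chain is
    testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
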