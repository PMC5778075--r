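Package: csiforecast
Title: Combined Heat-Drought Stress Index Modelling and Seasonal Yield
    Forecast Verification
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Calibrates country-level Combined Stress Index (CSI) models that
    explain interannual maize yield variability from two agro-climatic
    predictors, summer heat degree days (HDD) and the standardised
    precipitation-evapotranspiration index (SPEI), and verifies probabilistic
    low-yield forecasts derived from bias-corrected ensemble seasonal
    re-forecasts.  Includes a synthetic generator for gridded climate, crop
    masks, national yields with known climate sensitivity, and skill-tunable
    forecast ensembles; leave-one-out cross-validated ridge calibration with
    SPEI-window optimisation; non-parametric quantile mapping; and reliability,
    ROC skill score and Equitable Threat Score verification with bootstrap
    uncertainty.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    tools,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
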