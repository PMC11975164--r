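Package: pondcast
Title: Forecast-Informed Dilution Scheduling for Algal Raceway Ponds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Simulates microalgal biomass growth in well-mixed raceway ponds
    with a layered Beer-Lambert light model and temperature-by-irradiance
    growth and dark-loss rate surfaces, forecasts pond water temperature from
    surface meteorology with a zero-dimensional energy balance, and chooses
    daily culture dilution rates by evaluating a grid of harvest scenarios
    against ensemble weather forecasts. Ships a synthetic weather and
    ensemble-forecast generator, fixed and forecast-informed operating
    policies, treatment-comparison experiments, and evaluation statistics
    (Nash-Sutcliffe efficiency, one-way ANOVA on weekly production).
License: MIT
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    lubridate,
    purrr,
    readr,
    rlang,
    Rcpp,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    ncdf4,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
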