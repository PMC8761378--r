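Package: no2lockdown
Title: Lockdown Impact on Annual NO2 Exposure and Attributable Mortality
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A multi-stage pipeline for estimating the effect of the 2020
    traffic lockdown on annual nitrogen dioxide (NO2) exposure and
    NO2-attributable deaths at neighbourhood scale. Includes quality control
    and accuracy calibration for citizen-science passive-sampler campaigns,
    weather-normalised counterfactual prediction of lockdown-month NO2 with
    random forests and out-of-bag prediction intervals, annualisation of
    one-month measurements via station-derived adjustment factors, land-use
    random forest spatial prediction on city grids from multi-radius buffer
    predictors, and census-block health impact assessment with an
    attributable-fraction dose-response model and uncertainty propagation.
    A synthetic-city generator with known injected lockdown effect supports
    end-to-end validation without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    ranger,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
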