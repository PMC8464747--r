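Package: pasturegrow
Title: Daily Weather-Driven Pasture Growth Modelling and Validation
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A simple mechanistic pasture growth model driven only by site
    latitude, daily minimum and maximum air temperature, and precipitation.
    The model runs on daily time steps: it maintains a plant-available soil
    water bucket fed by rainfall and drained by evapotranspiration estimated
    from a pan-evaporation surrogate, applies trapezoidal cardinal-temperature
    and daylength growth responses, gates spring growth initiation on
    accumulated thermal time, and sums the daily product of four relative
    growth rate factors into a season-long index of growing-condition quality.
    Includes model validation statistics (regression of observed on modelled
    growth with R-squared, residual standard deviation, and average absolute
    percent error), a seeded synthetic weather and observation generator for
    testing, climate-scenario perturbation, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
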