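Package: hogwind
Title: Mechanistic Wind-Dispersal Models for Giant Hogweed Propagules
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Mechanistic models of wind dispersal for propagules (mericarps)
    of the invasive hogweed Heracleum sosnowskyi: a simple ballistic flight
    model, a wind-gradient model based on the Hellmann power-law wind
    profile, calibration of the Hellmann exponent against field launch
    experiments, and a stochastic individual-based dispersal-kernel
    simulator driven by weather-station wind records. Includes propagule
    trait computation (wing loading, terminal velocity from timed drops),
    a synthetic-data generator reproducing the statistical structure of
    the field measurements, CSV schemas for all inputs, and a command-line
    interface.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
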