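Package: barnsense
Title: Simulation and Analytics for Multi-Sensor Environmental Monitoring in Livestock Housing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing and validating IoT environmental monitoring of
    livestock housing. Provides a synthetic barn simulator (well-mixed zone gas
    mass balance with diurnal climate and feeding-event pulses), a virtual
    multi-sensor node with multi-rate sampling, ten-minute aggregation and a
    compact binary telemetry codec, electrochemical sensor span/zero calibration
    and multi-device repeatability assessment, gateway store-and-forward
    buffering with hourly/daily resampling and temperature-humidity index (THI),
    welfare threshold and spatial-uniformity analytics, and an ammonia emission
    estimator based on the carbon dioxide tracer-gas balance with herd-based
    metabolic CO2 production.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    zoo
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
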