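Package: spatgran
Title: Optimal Areal-Unit Selection and Kriging for Outdoor Sensor Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing spatially distributed outdoor-sensor
    observations such as air-quality monitoring networks. Points are
    aggregated into regular hexagonal areal units at candidate scales; each
    scale is scored by Global Moran's I and by the coefficient of variation
    of Local Moran's I (LISA), and the optimal spatial granularity is chosen
    by Pareto non-dominated sorting of the two conflicting criteria, a
    principled response to the modifiable areal unit problem. The package
    also provides the companion interpolation workflow: data normalisation,
    empirical variogram estimation, theoretical variogram fitting, ordinary
    Kriging of pollutant fields and indicator Kriging of threshold-exceedance
    probabilities, together with Air Quality Index (AQI) computation from
    breakpoint tables, a reader for the US-EPA daily pollution CSV layout and
    a seeded generator of spatially autocorrelated synthetic sensor data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
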