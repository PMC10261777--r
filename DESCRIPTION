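Package: rehydkin
Title: Rehydration Kinetics Modelling and Quality Analysis of Dried Sweet Corn
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits the Peleg, Weibull and logarithmic rehydration models to
    moisture-versus-time soaking curves of dehydrated sweet corn kernels,
    computes goodness-of-fit statistics (R-squared, RMSE, reduced chi-square)
    and Peleg equilibrium moisture, derives physical quality metrics
    (rehydration ratio and rate, geometric mean diameter, CIELAB total
    color difference), and clusters blanching-by-temperature treatments by
    their standardized property profiles into dendrograms. A seeded
    synthetic-data generator reproduces the study design (four blanching
    pretreatments by four drying temperatures, five-minute sampling) so the
    whole pipeline is testable without raw measurements.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    stats,
    utils,
    jsonlite
Suggests:
    ape,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
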