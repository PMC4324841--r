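Package: voltigen
Title: Degree-Day Voltinism of Spodoptera litura on Peanut Under Climate
    Scenarios
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Predicts the number of generations (voltinism) and generation
    time of the tobacco caterpillar Spodoptera litura on peanut from daily
    maximum and minimum air temperatures, using growing degree-day
    accumulation with a lower developmental threshold, a horizontal upper
    cut-off, and a fixed thermal constant per generation, over the standard
    crop-season window (standard weeks 26-44). Includes a seeded sinusoidal
    daily weather surrogate for GCM-downscaled temperature replicates under
    SRES emission scenarios and future periods, readers and writers for
    DSSAT-dialect daily weather files, replicate-level summaries with
    equal-variance t-tests, and ANOVA sum-of-squares partitioning of
    prediction variance across location, period, climate model and scenario.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
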