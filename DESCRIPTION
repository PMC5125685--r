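Package: egsmodel
Title: Temperature-Adaptive Modelling of the End of the Growing Season
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Predicts the end of the growing season (EGS) for temperate
    Northern Hemisphere vegetation from daily mean air temperature. Leaf
    senescence is triggered, after midsummer, on the first day the 10-day
    trailing running-mean temperature falls below a critical threshold that
    adapts linearly to the local mean annual temperature. The package
    provides the adaptive-threshold model together with the classical
    fixed-threshold phenology rules of the IBIS dynamic vegetation model,
    biome-wise calibration of the threshold parameters by coarse-to-fine
    grid search on an error-sum-of-squares objective with a random
    calibration/validation pixel split, a validation suite (R-squared,
    RMSE, mean absolute error, cumulative within-k-day agreement, empirical
    per-pixel thresholds, interannual trends), a synthetic gridded-data
    generator with known ground truth for parameter-recovery experiments,
    and plain-text readers, writers and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
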