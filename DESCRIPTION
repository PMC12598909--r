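Package: peatflux
Title: Chamber Greenhouse-Gas Flux Processing and Budgets for a Cultivated
    Arctic Peatland
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: End-to-end processing of automatic-chamber greenhouse-gas
    measurements on a drained, cultivated peatland along a water-table
    gradient: dynamic-window linear flux computation from 1-Hz chamber
    closure traces with quality flagging, random-forest gap-filling with
    chamber-grouped cross-validation and per-tree bootstrap uncertainty,
    Michaelis-Menten light-response fits with light compensation points per
    water-table bin, GWP100 seasonal and annual budgets with net carbon
    balance, and mixed-effects ANOVA with interaction pruning. Includes a
    synthetic campaign generator with known ground truth (polar-day
    radiation, plot-specific water-table drawdown, fertilization pulses of
    nitrous oxide) used throughout the test suite.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    randomForest,
    lme4,
    lmerTest,
    car,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
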