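Package: adaptiveTI
Title: Adaptive Resource Allocation for Thermodynamic Integration Free
    Energy Calculations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing dV/dlambda gradient time series from
    alchemical thermodynamic integration (TI) simulations and for deciding,
    on the fly, how much sampling each lambda window needs. Implements
    automatic equilibration detection by maximising the effective sample
    size, decorrelation by statistical-inefficiency subsampling, a
    Jensen-Shannon histogram-distance convergence test with capped
    iterative extension, Gauss-Legendre and trapezoid lambda schedules,
    bootstrap gradient averaging, relative and absolute binding free
    energy cycle assembly with the analytic Boresch restraint release
    term, and replicate-level evaluation statistics (MAE/RMSE/R-squared,
    permutation tests, batch resampling, truncation analysis). A seeded
    synthetic gradient-stream backend allows the full controller to be
    exercised without a molecular dynamics engine.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    pracma,
    jsonlite,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
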