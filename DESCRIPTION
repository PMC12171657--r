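Package: epbsim
Title: Exponential-Poisson-Binomial Simulation of Actual and Charged Recidivism
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates long-run criminal recidivism under incomplete
    ascertainment (the "dark figure" of crime). Each offender's annual
    offense count is Poisson with a mean drawn from an Exponential
    population; offenses are charged independently with probability r
    (Binomial thinning); the odds of reoffending decline by a fixed
    fraction d each year via a deterministic hazard recurrence. Provides a
    vectorised Monte Carlo engine, an exact analytic engine based on
    Poisson thinning and Gauss-Legendre quadrature over the Exponential
    frailty, calibration of the population mean to an observed cumulative
    charged rate by bracketed root-finding, scripted scenario tables and
    trajectory exports, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    optparse,
    pracma,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
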