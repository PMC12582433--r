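Package: prevpde
Title: Lifetime Prevalence of a Chronic Disease from Aggregated Rates via an Illness-Death Model
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates age-, sex- and calendar-year-specific lifetime prevalence of a
    chronic condition (for example cancer) from aggregated registry tables of incidence,
    mortality and an initial prevalence profile.  The estimator integrates the
    illness-death-model partial differential equation along its characteristic lines,
    converting five-year age-group tables into continuous rate surfaces by linear
    interpolation, and multiplies the resulting prevalence surface with population
    counts to obtain absolute survivor numbers.  Includes a parametric synthetic-scenario
    generator with exactly known true prevalence and a stochastic three-state
    microsimulation that serves as an independent validation oracle for the solver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    deSolve
Config/testthat/edition: 3
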