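Package: foodcascade
Title: Shock Propagation on Calorie Trade Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates how shocks to domestic food production propagate
    through a weighted directed network of international calorie trade.
    Provides a data model for calorie trade networks with baseline
    demand accounting, a seeded synthetic network generator that
    emulates the topology of the observed 2013 food trade network, a
    cascade engine in which deficit-holding countries cut exports in
    inverse proportion to partner GDP, batch shock experiments yielding
    exposure, hedging, reserve and vulnerability measures, node-level
    topology covariates (including directed ANND/ANNS assortativity),
    and censored (Tobit), negative binomial and least squares
    regressions with heteroskedasticity-robust standard errors linking
    network position to simulated demand deficits.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    survival,
    MASS,
    sandwich,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
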