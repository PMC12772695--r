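Package: adderSHS
Title: Stochastic Multi-Step Adder Models of Cell Size Homeostasis with
    Saturating Growth
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Exact event-driven simulation and closed-form steady-state
    moments for stochastic hybrid models of cell size homeostasis in which
    cells grow under a Hill-type saturating growth law, progress through M
    stochastic cell-cycle stages whose transition hazard is proportional to
    the growth rate, and divide by a (possibly random) binary partition of
    size. Because the stage-transition hazard is proportional to the growth
    law, per-stage size increments are exactly exponential, which yields an
    exact (discretization-free) lineage simulator; an independent thinning
    simulator serves as a cross-validation oracle. The package also
    simulates proliferating clonal colonies (a branching process over both
    daughters) to quantify population-number and biomass noise, and
    provides analytic steady-state mean, second moment and squared
    coefficient of variation of cell size for any number of cycle stages.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
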