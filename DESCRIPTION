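Package: dropoutDesign
Title: D-Optimal Designs for Multiarm Longitudinal Trials with Dropout
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing multiarm trials with repeated measurements
    when participants may drop out before the end of follow-up. Computes the
    expected Fisher information of the fixed effects of a linear mixed model
    under available-case analysis with noninformative, design-dependent
    monotone dropout, searches for locally D-optimal designs (follow-up time
    points, group allocation weights, and dose levels) under restricted or
    flexible scheduling conditions and under fixed-budget cost constraints,
    and evaluates competing designs by Monte Carlo simulation of the
    resulting trials.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
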