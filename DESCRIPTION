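Package: phsgame
Title: Evolutionary Game Dynamics of Public Health Service Supervision
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Models the supervision of government-purchased public health
    services for older adults as an asymmetric evolutionary game between
    local governments (positive vs. passive supervision) and public health
    service institutions (self-discipline vs. fraud). Provides payoff-matrix
    construction, replicator dynamics under a static and three dynamic
    reward/penalty mechanisms, trajectory integration, equilibrium
    enumeration with Jacobian-based stability classification, regime
    classification, closed-orbit (center) analysis with a conserved first
    integral, cross-mechanism comparison and one-dimensional parameter
    sweeps, plus built-in scenarios and report generation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
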