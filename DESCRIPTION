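Package: hcosweep
Title: Conductance Screens and Correlation Analysis for a Leech Heartbeat
    Half-Center Oscillator Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a two-cell Hodgkin-Huxley-type half-center oscillator
    (HCO) model of leech heartbeat interneurons, screens its behaviour over a
    brute-force grid of eight key parameters (seven maximal conductances and
    the leak reversal potential), classifies every model instance as a
    half-center oscillator, endogenous burster, or one of several
    non-bursting activity types from its spike trains, and analyses the
    classified populations with principal component analysis, 3D orthogonal
    distance regression lines, two-sample Kolmogorov-Smirnov tests, and
    one-parameter family partitions. Includes a fast fixed-step
    exponential-Euler integration kernel, a resumable sweep store with
    database-style views, and synthetic-data generators for validating every
    analysis stage without large sweeps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Rcpp,
    deSolve,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
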