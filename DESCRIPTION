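Package: hemorheo
Title: Pharmacodynamic Analysis of Dipyrone Effects on Piglet Hemorheology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for single-dose pharmacodynamic studies of
    hemorheological time series, built around a piglet dipyrone (metamizole)
    study design. Implements linear-trapezoidal area under the effect curve
    (AUEC) over baseline and post-dose windows, the baseline-normalized A/B
    change ratio, paired baseline-versus-effect significance testing, relative
    standard deviation summaries, composite hemorheological indices linking
    blood parameters to the 4-methylaminoantipyrine (4MAA) metabolite, and a
    leave-one-out cross-validated model acceptance gate (Q2, PRESS, Q2asym,
    OECD-style criteria). A calibrated synthetic-cohort generator emulates the
    study's eight-piglet design for testing and power analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    deSolve,
    pracma,
    jsonlite
Config/testthat/edition: 3
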