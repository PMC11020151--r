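Package: mitohfpn
Title: Hybrid Functional Petri Net Simulation of Myometrial Mitochondrial
    Function Under Thiacalix[4]arene Inhibition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A hybrid functional Petri net (HFPN) engine and a ready-made model
    of isolated rat myometrial mitochondria responding to the thiacalix[4]arene
    C-1193: simultaneous NADH oxidation, inner-membrane electric potential,
    matrix Ca2+ accumulation (Fluo-4), nitric oxide synthesis (DAF-FM) and
    reactive oxygen species formation (DCF). Includes trajectory analysis
    (polynomial least squares, two-component linearization at a 2.5-min
    breakpoint, initial velocities), a Hill-coordinate estimator of the
    apparent inhibition constant with an R-squared acceptance filter, and a
    synthetic-data generator for replicate fluorescence time courses and
    dose-response tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
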