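Package: chondrotherm
Title: Cartilage Self-Heating Thermo-Mechanobiology Toolkit
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Models and simulation tools for studying loading-induced
    self-heating of cartilage-like dissipative hydrogels in a
    temperature-controlled compression bioreactor. Implements the
    saturating-exponential intra-articular temperature model with
    least-squares fitting and piecewise-ramp heater schedules, Prony-series
    linear viscoelasticity with hysteresis dissipation measures, mechanical
    characterization procedures (cycle-100 hysteresis area, equilibrium
    modulus from sequential stress relaxations), an axisymmetric coupled
    poro-viscoelastic and conjugate heat-transfer finite-element solver of a
    hydrogel sample in a culture well, first-order-plus-dead-time heater
    plant simulation with Ziegler-Nichols tuned PID tracking, comparative
    delta-delta-Ct qPCR fold-change analysis with Welch group comparisons,
    and seeded synthetic-data generators for every input so the full
    pipeline is testable without laboratory data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
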