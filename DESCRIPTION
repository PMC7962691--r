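Package: opcflow
Title: Gas-Dynamic Characterization of the Jet-Flow Overpressure Chamber
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Desk-scale physical characterization of the jet-flow
    overpressure chamber (OPC) used as a laboratory model of traumatic
    brain injury. Provides closed-form ideal-gas, normal-shock and
    blast-wave relations; a quasi-one-dimensional compressible
    finite-volume simulation of the diaphragm-burst venting event
    (driver blowdown, precursor wavelet, jet development, quasi-static
    equilibration); Pitot-static reduction of stagnation/static pressure
    pairs to Mach number, velocity and dynamic pressure; free-flight
    drag loading of a specimen-scale sphere; digital diagnostics of
    pressure-transducer records; and a seeded synthetic sensor-record
    generator so every analysis stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    deSolve,
    jsonlite,
    pracma,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
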