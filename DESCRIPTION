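Package: spicpms
Title: Single-Particle ICP-MS Signal Simulation, Event Detection and
    Quantification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for single-particle inductively coupled plasma mass
    spectrometry (sp-ICP-MS) data: simulation of time-resolved intensity
    traces with known ground truth (Poisson particle arrivals, lognormal
    sizes, ionic background, coincidence), iterative mean + k-sigma
    particle event detection over the ionic background, ionic sensitivity
    and transport-efficiency calibration, conversion of events to particle
    masses, spherical-equivalent diameters and number/mass concentrations,
    determination of the coincidence-limited critical particle count from
    a serial-dilution ladder, and spike-recovery / particle-ion partition
    metrics for evaluating tissue pretreatment methods.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
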