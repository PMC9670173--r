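Package: ionoacoustics
Title: Ionoacoustic Range Verification for Pulsed Proton Beams
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and signal-processing toolbox for ionoacoustic
    (protoacoustic) range verification in proton therapy. Models the pressure
    signal a pulsed proton beam produces at an ultrasound detector from its
    dose deposition in water (analytic Bragg-curve dose engine, spherical
    integration of the initial pressure, causal band-pass detector surrogate),
    denoises measurements with a simulated-template matched filter, quantifies
    signal-to-noise ratio with a dose-limited metric, estimates the Bragg-peak
    range by time-of-flight between the direct and window-reflected acoustic
    arrivals, and reproduces pulse-duration and beam-current optimization
    studies for preclinical (20 MeV) and clinical (70-260 MeV) beam energies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    signal,
    jsonlite,
    yaml,
    pracma,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
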