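Package: s3sim
Title: Hemodynamics-Driven Simulation of the Third Heart Sound
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Closed-loop lumped-parameter (0D) simulation of the human
    circulation coupled to a one-degree-of-freedom cardiohemic vibration
    model of third heart sound (S3) generation. The circulation model uses
    time-varying elastance chambers, quasi-steady orifice valves and
    windkessel arterial beds with homeostatic pressure-flow regulation.
    At the peak of early-diastolic atrioventricular inflow the momentum of
    the incoming blood column excites a damped mass-spring-dashpot system
    whose free vibration is the S3 waveform. The package simulates
    physiological (rest, exercise, aging) and pathological (valve
    regurgitation and stenosis, septal shunts, diastolic heart failure)
    conditions, and provides phonocardiogram-style signal analysis:
    band-energy spectra, dominant frequency, band-pass preprocessing and
    EBU R 128 / ITU-R BS.1770 integrated loudness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    pracma,
    signal,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
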