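Package: ssadose
Title: Monte Carlo Dosimetry for Spot-Scanning Aperture Proton Therapy
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Desk-scale condensed-history Monte Carlo transport of proton
    pencil beamlets through a range-shifter / collimating-aperture / water
    phantom geometry, for studying spot-by-spot beamlet collimation
    (a spot-scanning aperture, SSA) in pencil beam scanning proton therapy.
    Provides proton stopping-power and range services from embedded reference
    tables, a synthetic beam model and treatment-plan generator, voxelized
    dose and dose-averaged LET scoring, downstream dosimetric analyses
    (integrated depth dose, Bragg-peak spot size, peak-to-entrance ratio,
    beamlet transmission, exit energy spectra), a calibrated thick-target
    secondary-neutron dose estimator, and a delivery-time overhead model.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
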