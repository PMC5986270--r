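Package: protonflux
Title: Quantification of Transmembrane Proton Flux, Carbonic Anhydrase
    Activity and Proliferation Readouts from Cell-Physiology Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the quantitative analysis chain used in studies of
    monocarboxylate-transporter (MCT) mediated lactate/H+ cotransport and its
    facilitation by carbonic anhydrase II. Implements ratiometric (SNARF-type)
    pH calibration by Boltzmann sigmoid fitting and inversion, ion-sensitive
    microelectrode calibration, conversion of pH traces to intracellular
    proton concentration, maximal-slope transport-rate extraction, intrinsic
    buffer capacity and proton-flux computation from CO2/HCO3- pulses,
    the 18O isotope-exchange mass-spectrometric carbonic anhydrase activity
    assay (log-enrichment statistic and enzyme units), and a nuclei-counting
    proliferation readout (threshold, watershed, particle filtering,
    nuclei per square millimetre). A set of seeded synthetic-data generators
    with recorded ground truth emulates each experiment type so that every
    estimator can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    jsonlite,
    yaml,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
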