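Package: hfotools
Title: Automated High-Frequency Oscillation Detection and Epileptogenic
    Zone Delineation in Intracranial EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects ripples (80-200 Hz) and fast ripples (200-500 Hz) in
    intracranial EEG by consecutive-peak amplitude thresholds over a
    baseline estimated from the modal peak amplitude, removes
    filtering-induced false oscillations (Gibbs artefacts) by
    accumulating frequency-offset power differences of Morlet
    time-frequency spectra, and delineates the epileptogenic zone from
    the continuous resection ratio of high-order HFO channels.  Includes
    minimal EDF input/output, bipolar montage construction, slow-wave
    segment selection, detector parameter optimization by the Youden
    index, outcome-group statistics, and a synthetic iEEG generator with
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    signal,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
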