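Package: pottremor
Title: Accelerometer-Based Quantification of High-Frequency Orthostatic Tremor
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying high-frequency (13-18 Hz) orthostatic
    tremor from short triaxial accelerometer recordings. Implements the
    vector-magnitude transform, zero-phase fourth-order Butterworth band-pass
    filtering (10-22 Hz), FFT power spectra, in-band spectral peak
    identification, and a normalized tremor-dominance statistic, together
    with load-response characterization on an incremental leg-press schedule
    (load threshold, frequency stability, amplitude modulation), descriptive
    cohort summaries, and a fully seeded synthetic-recording generator with
    a 1/f sensor-noise floor for validation and parameter-recovery studies.
License: MIT
Encoding: UTF-8
Imports:
    signal,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
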