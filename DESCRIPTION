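Package: whiskres
Title: Spike-Train and Whisker-Kinematics Analysis of Cerebellar Resonance
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for cerebellar Purkinje-cell spiking and
    whisker movement under rhythmic optogenetic stimulation. Provides
    kernel-based instantaneous simple-spike frequency estimation,
    single-unit quality control, zero-phase Butterworth filtering, whisker
    protraction/retraction event detection with an amplitude threshold,
    Morlet continuous-wavelet-transform power spectra, a builder for
    pulse-train stimulation protocols, stimulus-aligned response averaging,
    resonance tuning curves, and entrainment-slope quantification.
    Includes a synthetic-data generator (a resonant second-order whisker
    plant and an inhomogeneous-Poisson spike-train simulator) so the whole
    pipeline is testable without recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    pracma,
    withr
Config/testthat/edition: 3
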