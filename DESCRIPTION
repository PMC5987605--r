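Package: rn400
Title: Rapid-N400 Brain Vital Sign Simulation and Sensor-Level Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and sensor-level analysis of the rapid N400 semantic
    incongruity response as elicited by compressed auditory tone/word-pair
    sequences. Provides a synthetic M/EEG cohort generator (evoked templates,
    induced beta desynchronization, ocular artifacts, 1/f background noise),
    zero-phase filtering, resampling, epoching and conditional averaging,
    recursive-least-squares EOG artifact removal, global field power with
    sign-flip permutation interval statistics, Morlet wavelet time-frequency
    maps with permutation T-statistics, and individual-level classification of
    congruent versus incongruent trial-averaged waveforms with a radial-kernel
    SVM, cross-validation and a label-permutation null. Includes compact EDF
    and tab-separated event file I/O and an end-to-end pipeline runner.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    signal,
    e1071,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
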