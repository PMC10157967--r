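Package: planeeg
Title: Spectral Characterization of Planarian Surface EEG Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analysis pipeline for continuous surface-electrode
    electrophysiology from small invertebrates (planarians), covering
    zero-phase two-pass Hamming-window FIR filtering, fixed-length
    epoching, automatic statistical artifact rejection, DPSS multitaper
    power spectral density estimation on a logarithmically spaced
    frequency grid, aperiodic 1/f^x exponent fitting, and group-level
    inference by label-permutation tests with false-discovery-rate
    correction and Welch t-tests. Includes a fully seeded synthetic
    recording generator (power-law background, band-limited
    oscillations, myogenic spike artifacts, power-line contamination)
    so every stage is verifiable without original recordings, and
    readers/writers for EDF and delimited-text recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
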