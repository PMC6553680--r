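Package: fpquant
Title: Automated Detection and Quantification of Fasciculation Potentials
    in High-Density Surface EMG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects and characterises fasciculation potentials (FPs) in
    high-density surface electromyography (HDSEMG) grid recordings.
    Implements a noise-responsive amplitude-threshold pipeline: zero-phase
    bandpass filtering, perimeter- and bad-channel exclusion, empirical
    probability-threshold spike detection with zero-crossing segmentation,
    cross-channel super-channel merging, classification against a local
    noise band via a linear amplitude inclusion threshold, exclusion of
    noisy five-second blocks, voluntary-train filtering, and per-recording
    frequency summaries.  Ships the validation machinery (manual/automated
    event matching, median ROC curves with AUC, repeated k-fold
    cross-validation of the threshold coefficient, weighted least-squares
    noise-versus-threshold regression) and a seedable synthetic HDSEMG
    generator with ground-truth annotations.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    signal,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
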