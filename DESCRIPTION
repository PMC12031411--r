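Package: cagevibe
Title: Vibration-Based Non-Contact Activity Classification for Rodent Home-Cage Monitoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for classifying the physical activity of a mouse in its home
    cage from the vibrations the animal induces in the cage structure, measured
    by a six-axis IMU mounted on a resonant (tuned-beam) cantilever. Provides a
    synthetic tuned-beam vibration simulator with a paired 30 Hz behavioural
    label stream, multi-level discrete wavelet feature extraction with
    max-pooled resampling, inverse-variance sensor fusion of resonance-coupled
    axes, a decision-tree reference labeller for per-frame behaviour exports, a
    CNN-LSTM activity classifier trained with Adam, and analytics for signal
    power, SNR, classification metrics and long-term activity timelines.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    caret,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
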