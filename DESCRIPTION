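Package: leakmend
Title: Symmetric Leakage Correction and Envelope Connectomes for Multichannel Oscillatory Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Removes zero-lag signal leakage among multiple region time-courses by
    symmetric (Loewdin) orthogonalisation -- the closest set of mutually orthogonal
    vectors to the originals in the least-squares sense -- and infers functional
    networks from the band-limited power envelopes of the corrected signals using
    Gaussian graphical models: full and partial correlation, L1-regularised precision
    estimation (graphical lasso) with cross-validated penalty selection, empirical-null
    calibration of edge scores, fixed-effects group inference, and false discovery
    rate thresholding. Includes a generative simulator of networked oscillatory
    sources (linear stochastic network dynamics driven by binary Poisson bursts,
    carrier oscillators, zero-lag linear mixing, additive noise) and AR(1) surrogate
    null data for calibration studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    signal,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
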