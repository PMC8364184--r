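Package: mscinet
Title: Multisensory Causal Inference in a Two-Stream Visual-Vestibular Network
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An in-silico study of how multisensory neurons can solve causal
    inference. The package synthesises naturalistic visual motion sequences
    and random-dot kinematograms with exact velocity ground truth, encodes
    self-motion as noisy Gaussian vestibular population codes, and trains a
    small two-stream feedforward network (V1 -> MT and vestibular -> PIVC
    streams converging on an MSTd layer) to estimate self-motion ("fusion"),
    scene motion ("scission") and a binary common-cause decision. It then
    characterises the trained multisensory units (sinusoidal heading tuning,
    congruent/opposite classification, ROC neurometric thresholds against
    maximum-likelihood cue integration, connection-weight summaries,
    artificial lesions) and runs network psychophysics (reliability-based
    cue weighting, causal-inference decision bias). The forward pass and
    back-propagation are implemented natively (RcppArmadillo, im2col + BLAS).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    tiff
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
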