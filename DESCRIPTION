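Package: momdecode
Title: Inverted Encoding and SSVEP Analysis of Predictable Orientation Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study anticipatory biases (representational momentum) in
    the neural encoding of rotating orientation sequences. Implements a
    synthetic generator for two-stream 5 Hz flickering-grating EEG experiments
    with known ground truth, an inverted encoding model (18 half-wave
    rectified cosine^18 orientation channels, noise-covariance-aware
    inversion, sliding-window leave-one-out decoding, channel tuning function
    realignment and Gaussian bias fits), SSVEP spectral analysis with
    lateralization flipping and electrode selection, global field power,
    cluster-based permutation tests (channel-shift surrogates, time-resolved
    repeated-measures ANOVA, electrode-time sign-flip maps), jackknife
    standard errors, and behavioral same/different analysis, orchestrated by
    a reproducible pipeline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    MASS,
    minpack.lm,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
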