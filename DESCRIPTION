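Package: squigq
Title: Quantum-Assisted Feature Extraction for Nanopore Squiggle Signals
Version: 0.1.0
Authors@R:
    person("squigq", "developers", email = "squigq@example.org", role = c("aut", "cre"))
Description: Tools to study quantum-circuit approaches to feature extraction
    from Nanopore squiggle current traces. Provides plain-text squiggle I/O
    and a synthetic trace generator with planted features; dimensionality
    reduction via sample duplication, a multilevel discrete wavelet
    transform, clamping and quantization with register sizing; classical
    detectors for near-to-constant, sharp-increase, sharp-decrease, peak and
    valley windows; a dense statevector simulator for reversible circuits
    over X/H/Z/CX/CCX/multi-controlled gates including ripple-borrow
    subtraction and two's-complement absolute value with an optional
    bit-flip noise channel; Grover-search detectors whose oracles mark
    threshold violations among superposed pairwise differences; and the
    accompanying error-propagation (w^s accumulation, repetition-code
    majority vote) and circuit breadth/depth/volume resource models.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
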