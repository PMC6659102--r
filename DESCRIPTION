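Package: lfpmodes
Title: Mode Decomposition and Network-Dynamics Metrics for Hippocampal
    Electrophysiology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Signal-analysis toolchain for characterizing hippocampal network
    dynamics from extracellular, juxtacellular and whole-cell recordings.
    Decomposes local field potentials into intrinsic mode functions (EMD and
    CEEMDAN), assembles theta/low-gamma/high-gamma band signals by mean
    instantaneous frequency, and computes Welch spectra, band-relative power
    and band occurrence statistics. Extracts multi-unit spike times, computes
    spike-triggered average LFPs and peri-spike band-power profiles, scores
    interspike-interval bursts and firing-rate decompositions, detects
    spontaneous synaptic currents with a sliding-template algorithm, fits
    evoked-current kinetics and toxin-sensitive component fractions, and
    scores three-chamber and open-field behavioral sessions. Seeded synthetic
    generators with ground-truth records make every stage testable without
    recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    signal,
    stats,
    utils,
    jsonlite,
    minpack.lm
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
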