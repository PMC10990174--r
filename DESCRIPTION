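Package: camposc
Title: Mixed-Mode Oscillations in a cAMP-Modulated Cortical Neuron Model
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Conductance-based model of a cortical pyramidal neuron in which
    cAMP modulates HCN and M-type potassium channels. Provides a five-variable
    Hodgkin-Huxley-type model with drug-condition presets, fixed-step and
    adaptive integration, detection and classification of large- and
    small-amplitude oscillations, mixed-mode-oscillation signatures, firing
    frequency curves and regime scans over applied current. Includes the
    reduction to a three-variable slow-fast subsystem by averaging the
    super-slow gates, one- and two-parameter bifurcation analysis (Hopf,
    period doubling via Floquet multipliers, attractor scans), and the
    geometric singular perturbation machinery: closed-form critical manifold
    and fold curves, desingularized reduced flow, folded singularities,
    canard orbits by slow-manifold reconstruction, and rotational-sector
    prediction of small-oscillation counts.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    deSolve,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
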