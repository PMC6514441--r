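Package: tspn
Title: Conductance-Based Modelling of Thoracic Sympathetic Postganglionic Neurons
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Single-compartment Hodgkin-Huxley style model of thoracic sympathetic
    postganglionic neurons (tSPNs) with nine membrane currents (Na, Kd, M, KCa, A, H,
    CaL, leak, and an impalement-injury leak), intracellular calcium dynamics and an
    exponential-Euler integrator. Ships virtual-experiment protocols (bias-current
    holding, rheobase binary search, strength-duration curves, f-I curves,
    firing-type phase diagrams under simulated microelectrode impalement, conductance
    knockouts, Poisson synaptic-conductance drive), a patch-clamp feature-extraction
    pipeline (passive-property fits, spike threshold, action-potential and
    afterhyperpolarization metrics, firing rates and spike-rate adaptation,
    sag/rebound/notch detection), a synthetic-population generator emulating recorded
    cell heterogeneity, and Pearson correlation statistics with Sidak correction.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    minpack.lm,
    yaml,
    stats,
    graphics,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
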