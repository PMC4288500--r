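Package: kmburst
Title: Kv7/M-Current and BK Channel Pharmacology with Burst-Firing Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying pharmacological modulation of M-type
    (Kv7/KCNQ) and large-conductance Ca2+-activated (BK) potassium channels
    and its consequence for neuronal burst firing.  Provides seeded
    generators for synthetic patch-clamp data (whole-cell step protocols,
    concentration-response tables, stochastic single-channel records,
    action-current trains), Hill and Boltzmann curve fitting with gating
    charge, single-channel idealization and open-probability (NPo)
    estimation, action-current detection, a single-compartment
    conductance-based CA3 pyramidal-neuron burst simulator with scalable
    g_M and g_KCa, burst metrics (intraburst rate, interburst
    afterhyperpolarization), and fast-slow decomposition of bursting on the
    plane of the two slow gating variables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    minpack.lm,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
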