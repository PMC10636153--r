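Package: laminattn
Title: Layer- and Cell-Class-Specific Analysis of Attentional Modulation of
    Contrast Responses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing laminar extracellular recordings from visual
    cortex under spatial attention: waveform-based classification of single
    units into narrow-, medium- and broad-spiking classes (peak-to-trough
    duration, consensus k-means, AIC/BIC model selection, Hartigan's dip
    test, PCA cross-check), hyperbolic-ratio contrast-response-function
    fitting with attentional modulation (AMI) and contrast-dependence (CDI)
    indices, response-latency estimation with adaptive-bandwidth kernel rate
    estimates, bootstrap estimation statistics, a normalization model of
    attention with stimulation/suppressive/attention-field sweeps, and a
    columnar conductance-based excitatory-inhibitory spiking network with
    pooled spike-train cross-correlogram readout.  A synthetic-data
    generator emulates laminar V4 recordings so the whole pipeline runs
    end-to-end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
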