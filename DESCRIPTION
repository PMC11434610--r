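Package: thzneuron
Title: Terahertz Modulation of Potassium Conductance in a Cortical Neuron Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Conductance-based (Hodgkin-Huxley) simulation of a cortical
    pyramidal neuron in which high-frequency terahertz stimulation enters as a
    multiplicative enhancement of potassium conductance, together with the
    electrophysiology analysis chain used to characterise the effect:
    action-potential metrics (FWHM, firing rate, rheobase, resting membrane
    potential, F-I curves, phase plots), voltage-clamp step protocols with
    current-voltage, Boltzmann and leak-conductance fitting, extracellular
    unit classification (trough-to-peak rule and k-means) and pre/post
    stimulation firing-rate change testing. A synthetic-data module generates
    clamp traces, biphasic unit waveforms and Poisson spike trains with known
    ground truth so every analysis stage is testable as parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    withr
Config/testthat/edition: 3
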