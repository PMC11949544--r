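Package: spikewave
Title: Whole-Brain Neural Mass Simulation and Scoring of Interictal Spike-Wave EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulates scalp EEG from a whole-brain network of layered
    neocortical neural mass models coupled to a lumped thalamus through a
    delayed, connectome-weighted network, and projects regional layer-V
    synaptic currents to 10-20 scalp electrodes with a current-dipole
    leadfield. Includes an epileptic parameter regime producing 2-3 Hz
    spike-wave discharges, region fragmentation and virtual resection for
    in-silico surgery, an interictal spike detector with polarity labelling,
    a single-channel maximum cross-correlation similarity index, a
    seven-criterion scalp EEG spike-similarity score, and fully synthetic
    head geometry, connectivity and reference recordings so every pipeline
    stage runs without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
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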