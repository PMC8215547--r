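Package: lnnlab
Title: Hybrid Bio-Silicon Neural Network Simulation and Training
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how neural variability and random sparse
    connectivity affect inference in hybrid bio-silicon neural networks. The
    package simulates a biologically realistic "living" layer (two-compartment
    Pinsky-Rinzel neurons driven by alpha-function excitatory synapses),
    transfers its variability into a fast threshold-network model via the
    minimum-presynaptic-count (minPreNum) bridging experiment, trains the
    resulting sparse, sign- and range-constrained network with a windowed
    straight-through estimator, and provides an adaptive pre-processing method
    that tunes input density toward a target hidden-layer firing rate.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    nnet
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
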