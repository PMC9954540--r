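Package: p300bci
Title: Synthetic P300 Oddball Sessions and Riemannian, Case-Based and
    Quantum-Simulated Classification
Version: 0.1.0
Authors@R:
    person("p300bci", "maintainers", email = "p300bci@example.org",
           role = c("aut", "cre"))
Description: Tools for the binary classification of P300 event-related
    potentials in oddball brain-computer interface experiments. Generates
    synthetic multichannel EEG sessions following the Brain Invaders design
    (16 channels, 128 Hz, 2 TARGET and 10 NON-TARGET flashes per repetition),
    band-pass filters and epochs the record, estimates per-class xDAWN
    spatial filters, builds super-trial correlation matrices and projects
    them into the tangent space of the manifold of symmetric
    positive-definite matrices. Classifier families include a minimum
    distance to Riemannian mean baseline, a radial-basis support vector
    machine, a hypergraph case-based reasoning classifier, and exact
    statevector simulations of a variational quantum classifier and a
    quantum-kernel support vector classifier. A cross-validated evaluation
    harness provides balanced accuracy, stratified folds and permutation
    significance thresholds.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
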