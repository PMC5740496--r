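Package: stressgrn
Title: Perturbation-Based Inference of a Stress-Responsive Transcription Factor Network
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools to simulate and analyse small perturbation-based gene regulatory
    networks of the kind underlying mild-osmotic-stress growth inhibition in
    Arabidopsis leaves: a ground-truth network generator with Hill-kinetics ODE
    dynamics and negative-binomial probe-count emission, housekeeping-gene count
    normalization, stress time-course statistics with onset-group classification,
    edge calling from inducible-overexpression time courses, transient expression
    assay (luciferase) validation including pairwise-effector scenario
    classification, signed network motif detection (feed-forward loops, feedback
    cycles, hub coverage), and phenotype statistics including relative stress
    reduction and the log2-scale additivity test for genetic interactions.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
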