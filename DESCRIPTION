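Package: megbmi
Title: Simulation and Analysis of MEG Brain-Machine Interface Training,
    Sensorimotor Plasticity and Phantom Limb Pain
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale simulation and analysis pipeline for magnetoencephalography
    (MEG) based brain-machine interface (BMI) experiments on phantom limb pain.
    Generates synthetic multichannel sensor recordings from a toy cortical source
    space, performs cue-locked epoching, sliding-window averaging and baseline
    z-scoring, decodes two-class movement intentions with nested cross-validated
    radial-basis-kernel support vector machines including data-driven time-window
    selection, estimates per-vertex cortical currents with a hierarchical
    variational-Bayes inverse filter, maps movement discriminability with
    per-vertex one-way ANOVA F statistics, simulates closed-loop neuroprosthetic
    training that shifts cortical discriminability, and reproduces the group-level
    statistics relating training-induced plasticity to pain ratings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    data.table,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    e1071,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
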