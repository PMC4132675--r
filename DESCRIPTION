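Package: tcmvpa
Title: Tone-Cloud Learning Experiments and ROI-Based Multivoxel Decoding
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis pipeline for incidental auditory
    pattern-learning experiments. Synthesises tone-cloud stimuli on a
    time-frequency grid, builds training and test trial sequences for a
    within-trial repetition-detection task with d-prime scoring, generates
    synthetic region-of-interest fMRI data (trial-wise betas or BOLD time
    series) carrying exemplar-specific multivoxel patterns, estimates
    trial-wise betas by GLM with a canonical double-gamma HRF, and decodes
    learnt exemplars with searchlight feature selection, error-correcting
    output codes over linear support vector machines and stratified 10-fold
    cross-validation, including label-shuffle and pseudo-class controls and
    group-level inference.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
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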