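Package: hybridnf
Title: Simulated Closed-Loop Hybrid EEG-fMRI Neurofeedback
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A desk-scale, fully synthetic re-creation of a hybrid
    EEG-fMRI neurofeedback platform. Generates ground-truthed bimodal
    recordings (multichannel EEG contaminated with TR-locked gradient and
    heartbeat-locked ballistocardiogram artifacts, plus BOLD volume series
    with hemodynamic task activation), runs the full real-time processing
    chain (sliding-template artifact subtraction, band-pass filtering,
    common spatial patterns band-power features, incremental general
    linear model, activation mapping and region-of-interest selection),
    turns per-modality features into feedback values (percent signal
    change, z-scores, baseline tracking, unimodal and bimodal
    combination), and drives a two-layer synchronization engine with
    fixed and flexible block protocols on a deterministic simulated
    clock, closed through a simple self-regulating subject model.
    Includes BrainVision and NIfTI-1 readers/writers and deterministic
    feedback-display mappings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    RNifti,
    yaml,
    stats,
    utils,
    tools,
    graphics
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
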