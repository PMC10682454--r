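Package: restreact
Title: Resting-State Reactivation Analysis for Two-Photon Calcium Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects spatially-selective neurons and synchronous resting-state
    ensembles in deconvolved two-photon calcium-imaging recordings from head-fixed
    mice running on a cued treadmill belt, classifies ensembles as cue- or
    trajectory-encoding, and estimates per-ensemble reactivation strength with a
    seeded PCA-ICA decomposition (Marcenko-Pastur component selection followed by
    reconstruction ICA). Includes sharp-wave-ripple detection in hippocampal LFP,
    peri-ripple timing and cross-correlation lag analyses of cue versus trajectory
    reactivations, explained-variance and ensemble-persistence statistics, a
    Hopfield pattern-completion test on reactivated spatial features, and a
    synthetic-session generator with planted ground truth so that every stage of
    the pipeline can be validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    tools,
    signal,
    jsonlite,
    minpack.lm
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
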