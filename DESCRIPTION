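Package: neurokws
Title: Neural Keyword Spotting from Electrocorticographic High-Gamma Features
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A two-stage neural keyword-spotting pipeline for multichannel
    electrocorticographic (ECoG) recordings of overt speech. Causal
    high-gamma (70-110 Hz) band-power features are extracted with a sliding
    short-time Fourier transform and z-scored to a pooled pre-stimulus
    baseline; spatiotemporal matched-filter templates built from
    voice-onset-aligned response epochs drive a neural voice-activity
    detector (squared template correlation plus causal peak-picking) and a
    discriminative keyword-versus-non-keyword classifier (PCA-reduced
    template outputs, online max-margin passive-aggressive training).
    Includes a ground-truthed synthetic session generator for
    consonant-vowel syllable tasks, ROC/AUC evaluation with a
    scrambled-label permutation null, end-to-end simulated keyword
    spotting, and a command-line interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    data.table,
    jsonlite,
    stats,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
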