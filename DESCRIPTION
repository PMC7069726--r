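Package: thetagaze
Title: Fixation-Locked Hippocampal Theta and Theta-Gamma Coupling Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for linking eye movements to hippocampal
    field-potential oscillations: gaze parsing into saccade/fixation/blink
    events with threshold-based detection, bipolar referencing and
    fixation-locked epoching of intracranial EEG, Morlet and multitaper
    spectral decomposition with aperiodic (1/f) plus Gaussian-peak spectral
    modeling, inter-trial phase coherence with subsample-matched contrasts,
    circular phase statistics (Rayleigh, Watson-Williams with permutation),
    surrogate-normalized theta-gamma phase-amplitude coupling with
    waveform-shape confound regression, and nonparametric cluster-based
    permutation inference. Includes a seeded joint LFP + gaze simulator with
    known ground truth so every stage is validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    MASS,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
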