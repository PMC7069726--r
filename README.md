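# thetagaze

Fixation-locked analysis of hippocampal field-potential oscillations, for
researchers linking eye movements to memory-related neural dynamics in
intracranial recordings.

During natural viewing, hippocampal theta (4–6 Hz) is hypothesized to
coordinate memory with individual eye movements: phase-locking near the
theta **peak** precedes fixations that retrieve a stored object-location,
phase-locking near the **trough** follows fixations onto novel
(association-violating) content, and theta–gamma phase-amplitude coupling
increases when visual input conflicts with memory. Testing these
hypotheses requires a chain of estimators, each of which this package
implements and validates by parameter recovery on synthetic data with
known ground truth:

* **Eye-event parsing** — saccade/fixation/blink segmentation from 500 Hz
  gaze samples using joint velocity (30°/s), acceleration (8000°/s²) and
  motion (0.15°) thresholds; ROI labelling within 6°; viewing-proportion
  timecourses.
* **Preprocessing** — bipolar referencing, zero-phase Butterworth
  line-noise removal, anti-aliased downsampling to 500 Hz, and buffered
  fixation-locked epoching.
* **Spectral decomposition** — complex Morlet transform (wave number 5, 30
  log-spaced frequencies 1–10 Hz), DPSS multitaper spectra, an aperiodic
  (1/f) + Gaussian-peaks spectral model, and a surrogate-based permutation
  test for oscillation presence above the aperiodic background.
* **Phase-locking** — inter-trial phase coherence
  `ITC = (1/N)|Σ exp(iφ)|` with subsample-matched condition contrasts
  (removing the small-N bias `E[ITC] ≈ √π / 2√N`), circular means with
  dispersion CIs, Rayleigh and permutation Watson–Williams tests, and an
  ERP-based phase-reset check.
* **Phase-amplitude coupling** — the modulation index
  `MI = D_KL(P, U) / log N` over 20 phase bins, surrogate-normalized
  comodulograms (`MI_Z`, trial-shuffled phase surrogates), theta-frequency
  selection, and waveform-shape confound control (theta power, single-trial
  phase-locking, peak/trough sharpness, asymmetry) by multiple regression.
* **Statistics** — nonparametric cluster-based permutation inference with
  max-cluster-mass FWE control (exact sign-flip enumeration for small
  samples), electrode-proportion binomial tests, and Hedges' *g* for
  dependent samples.
* **Synthetic sessions** — a seeded generator of joint LFP + gaze + trial
  structure: 1/f background, theta with stochastic instantaneous
  frequency, gamma amplitude-coupled to a configurable theta phase and
  depth, fixation onsets phase-locked by a von Mises law per condition,
  and threshold-compliant saccade kinematics with blinks.

## Worked example

The `analysis/` directory is a numbered workflow over one synthetic
session (run from the repository root, in order):

```sh
Rscript analysis/01_simulate.R      # build the demo session
Rscript analysis/02_parse_eyes.R    # parse + label gaze
Rscript analysis/03_spectral.R      # 1/f model + theta presence
Rscript analysis/04_phase_locking.R # ITC + phase angles
Rscript analysis/05_pac.R           # comodulograms + confound control
Rscript analysis/06_group_report.R  # 7-subject group contrasts
```

The session programs peak-locking (κ = 4 at phase 0) 400 ms before
fixations to the "original" object-location, trough-locking (κ = 4 at
phase π) 100 ms after fixations to the "updated" location, and theta–gamma
coupling (depth 0.8, 5 Hz → 90 Hz) on Mismatch trials. The workflow
recovers all of it:

```
Programmed saccades >= 1 deg: 201; recovered within 4 ms: 100.0%
Aperiodic fit: offset 0.03, exponent 1.52; 4 peak(s)      # true exponent 1.5
Theta presence (pre-fixation, 128 epochs): F = 1.73, p = 0.0004998
5 Hz ITC peaks: original-class at -426 ms (ITC 0.65), updated-class at +50 ms (ITC 0.68)
Pre-window phase (original class): mean 0.05 rad, 95% CI [-0.27 0.36]   # peak
Post-window phase (updated class): mean -2.76 rad, 95% CI [-3.09 -2.43] # trough
Watson-Williams: F = 110.4, Z_F = 17.0, permutation p = 0.000999
Mismatch comodulogram: max MI_Z = 43.0 at 5.2 Hz phase x 87 Hz amplitude
Selected theta frequency (4-6 Hz, pooled): 5.2 Hz
```

and the group stage flags all four programmed effects with
Bonferroni-corrected cluster inference:

```
Session flags:  retrieval TRUE   novelty TRUE   phase_angle TRUE   pac TRUE
  retrieval: min cluster P_FWE = 0.007812
  phase_angle: Z_F = 37.3, permutation p = 0.001996
```

The ITC peak latencies sit at the programmed lock offsets, the phase means
at the programmed peak/trough, and the comodulogram maximum at the
programmed frequency pair — within one frequency-grid step.

See `vignettes/methods.Rmd` for the underlying models, estimator choices
and their calibration story.

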