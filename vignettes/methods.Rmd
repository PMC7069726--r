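---
title: "Fixation-locked hippocampal oscillation analysis: models, estimators, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fixation-locked hippocampal oscillation analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific problem

During natural viewing, the hippocampus is hypothesized to coordinate
memory encoding and retrieval with individual eye movements: fixations that
retrieve a stored object-location association should be preceded by
phase-locking of the hippocampal theta rhythm (4–6 Hz) near its *peak*,
whereas fixations onto novel, association-violating content should be
followed by phase-locking near the theta *trough*, accompanied by increased
theta–gamma phase-amplitude coupling. Testing such hypotheses requires a
chain of estimators — eye-movement parsing, fixation-locked spectral
decomposition, phase-coherence and coupling statistics, and nonparametric
cluster inference — each of which can silently bias the result.

`thetagaze` implements this analysis chain together with a joint
LFP-plus-gaze simulator whose ground truth (theta phase at every sample,
the locked phase of every fixation, the coupling phase and depth) is known
exactly, so every stage is validated by parameter recovery rather than by
eyeballing. Throughout the package, phase is in radians in $(-\pi, \pi]$
with 0 at the oscillation peak and $\pm\pi$ at the trough.

## The synthetic session generator

`simulate_lfp()` builds the field potential as a sum of three components:

* **Aperiodic background.** Frequency-domain synthesis of a Gaussian
  process with one-sided spectral density $P(f) = 10^{\mathrm{offset}}
  f^{-\chi}$. Complex-Gaussian spectral coefficients are essential: a
  fixed-modulus random-phase construction is not a Gaussian process and its
  higher-order dependencies measurably bias phase–amplitude statistics.
* **Theta.** $A_\theta \cos\theta(t)$, where the instantaneous frequency
  performs an Ornstein–Uhlenbeck excursion around `theta_freq`
  (stationary SD `theta_freq_sd`, default 0.8 Hz, time constant 0.3 s). The
  drift gives theta a finite phase memory, so phase-locking imposed at one
  instant decays over a few hundred milliseconds — without it, locking at
  fixation onset would be visible at *every* peri-fixation latency and the
  pre- versus post-fixation contrasts that motivate the analysis would be
  undefined. The default drift makes onset-locked coherence decay to near
  baseline by ±400–500 ms, similar to empirical fixation-locked ITC
  profiles, while leaving a credible 4–6 Hz spectral peak.
* **Gamma.** A carrier at `gamma_freq` whose instantaneous amplitude
  follows the normalized cosine law
  $A_\gamma\,[1 + d\cos(\theta(t) - \varphi_c)]/(1+d)$, so `coupling_depth`
  $d = 1$ silences gamma at the anti-preferred phase and $d = 0$ removes
  the coupling entirely. The coupling depth may vary by trial condition
  (`coupling_depth_by_condition`), which is how condition-specific PAC
  effects are built into a session.

Default amplitudes (`theta_amp = 1`, `gamma_amp = 0.25` against the
`offset = 0`, $\chi = 1.5$ background) put the theta peak a factor ~2 above
the background at 5 Hz and gamma slightly below the local background — the
regime in which comodulogram localization is meaningful. If the gamma
component dominates the background, wavelet bandwidth leaks the modulated
carrier across the whole 80–200 Hz axis and *any* estimator with
finite-bandwidth amplitude filters produces a coupling plateau rather than
a peak; this is a property of the measurement physics, not of the
implementation.

**Fixation stream.** `simulate_fixation_stream()` thins a homogeneous
Poisson candidate stream: a candidate at time $t$ is accepted with the von
Mises probability $\exp\{\kappa[\cos(\theta(t+\delta) - \mu) - 1]\}$, where
$\kappa$, $\mu$ and the lock offset $\delta$ are per condition (or
condition/ROI class), followed by a non-paralyzable minimum spacing that
guarantees fixation durations of at least 80 ms. Both thinning steps are
rate-compensated per trial — the von Mises acceptance by its exact mean
$e^{-\kappa} I_0(\kappa)$ and the dead time by $\lambda/(1-\lambda\tau)$ —
so the accepted rate equals `fixation_rate` in every condition. Rejection
sampling (rather than deterministic phase-triggered placement) preserves
Poisson-like inter-fixation statistics.

**Gaze.** `simulate_gaze()` renders 500 Hz samples: fixations hold position
with 0.02° jitter (safely below the 0.15° motion threshold), a compact
~30 ms raised-cosine saccade lands on the next target at its onset (peak
velocity $\pi A / 2T \geq 52$°/s and peak acceleration
$\pi^2 A / 2T^2 \geq 10{,}000$°/s² for amplitudes ≥ 1°, above both
detection thresholds), and blinks appear as pupil dropouts inside long
fixations. The generator's event and interval truth is attached for
recovery scoring.

What the generator deliberately does *not* emulate: saccadic main-sequence
amplitude–duration scaling beyond threshold compliance, volume conduction
across electrodes, epileptiform artifacts, and any dependence of gaze
behavior on the LFP beyond the programmed phase-locking. Passing the
recovery suite therefore demonstrates estimator correctness and
calibration under realistic spectra and event statistics — not robustness
to every pathology of clinical recordings.

## Eye-event parsing

`detect_eye_events()` classifies every sample as blink (pupil dropout,
padded by ±25 ms because eyelid artifacts corrupt velocity estimates),
saccade, or fixation — a partition with no gaps or overlaps. Velocity and
acceleration are estimated by central differences after a 3-sample median
filter (the robust minimal scheme at 500 Hz). A candidate saccade must
jointly exceed the velocity (30°/s), acceleration (8000°/s²) and motion
(0.15°) thresholds; accepted events are then extended to a lower hysteresis
threshold (max of 12°/s and 15% of peak velocity) so the reported onset
sits at the start of the velocity rise — without this, small saccades cross
the main threshold several milliseconds late. Fixations shorter than 80 ms
are kept but flagged `excluded`. ROI labelling assigns each fixation to the
nearest object-location center within 6°, with exact ties broken by a fixed
ROI ordering, and flags fixations within 500 ms of trial onset/offset as
outside the analysis window.

## Spectral estimators

* **Morlet transform** (`morlet_transform()`): analytic Gaussian kernels in
  the frequency domain, bandwidth $\sigma_f = f/\text{wave number}$ with
  wave number 5, over 30 log-spaced frequencies from 1 to 10 Hz by default
  (a geometric progression including both endpoints). Phase 0 corresponds
  to the waveform peak. Epochs carry a 1250 ms buffer that is transformed
  and then trimmed: at 1 Hz the wavelet's temporal SD is 0.8 s, so
  buffer-free estimates near window edges are extrapolations dominated by
  kernel roll-off. This matters quantitatively — see the MI_Z calibration
  note below.
* **Multitaper PSD** (`multitaper_psd()`): DPSS tapers from the standard
  tridiagonal eigenproblem, time–bandwidth 2 with 3 tapers (a conventional
  choice for ~1 s epochs). Long signals are split into ≤ 4096-sample
  segments whose tapered spectra are averaged, which bounds the
  eigenproblem and tightens the estimate.
* **Aperiodic + peaks model** (`fit_spectral_model()`): iterative robust
  regression of log-power on log-frequency that excludes putative peak
  bins, followed by greedy Gaussian peak fitting on the residual; a peak is
  kept only if it exceeds max(0.1, 2 SD) and reduces the global residual
  sum of squares, so the full model never fits worse than the aperiodic
  model and the variance-ratio statistic $F \ge 1$ by construction.

**Oscillation presence** (`test_oscillation_presence()`) asks whether a
band-limited rhythm exists above the 1/f background across fixations. Two
natural designs — resampling log-residuals across frequency bins within a
linear or quadratic aperiodic fit — turn out to be uncalibratable for
800 ms windows: with taper bandwidth $W = 2.5$ Hz, spectral smearing makes
low-frequency residuals both biased and heteroskedastic, so in-band and
out-of-band residuals are not exchangeable. The implemented design removes
the asymmetry at its root: for each fixation, a power-law model is fitted
*above* the band (8–60 Hz, where $W/f$ is small), a time-domain aperiodic
surrogate signal is synthesized from the fitted model, and raw and
surrogate pass through the *identical* spectral pipeline. The statistic
pools in-band residual RSS (band widened upward by $W$ to capture line
smearing) across fixations, $F = \sum A_i / \sum B_i$, and the null swaps
the raw/surrogate label per fixation. Every estimator bias is common to
numerator and denominator and cancels; measured type-I error is at the
nominal rate and power at a ~2:1 theta peak reaches 100% with 100 epochs.

## Phase-locking statistics

ITC is the magnitude of the mean unit phasor over events,
$\mathrm{ITC}_{ft} = \frac{1}{N}\lvert\sum_k e^{i\varphi_{ftk}}\rvert$.
Because $E[\mathrm{ITC}]$ under uniform phases is
$\approx \sqrt{\pi}/(2\sqrt{N})$, comparisons between conditions with
different event counts are biased; `itc_contrast_subsampled()` subsamples
the larger condition to the smaller $N$ and averages over 100 draws by
default (averaging reduces draw variance; a single-draw mode exists).

Circular summaries use the resultant-based mean with a dispersion
(Fisher-style) 95% CI, falling back to a percentile bootstrap when the
resultant length is below 0.1. The Rayleigh statistic is $Z = nR^2$ with
the standard large-sample tail approximation. The two-sample
Watson–Williams $F$ carries its concentration correction; inference uses a
label-shuffling permutation with $Z_F = (F_{obs} - \bar F_0)/s_{F_0}$ and
the exceedance proportion as p (1000 permutations by default).

The ERP-based phase-reset check compares multitaper power of the
across-event average ERP in the pre- (−750 to 50 ms) and post-fixation
(−50 to 750 ms) windows; the null exchanges the two segments within each
event before averaging, and the log power ratio is cluster-corrected over
frequency.

## Phase-amplitude coupling

The modulation index bins gamma amplitude by theta phase (20 bins of 18°),
normalizes the bin means to a distribution $P$, and computes
$\mathrm{MI} = D_{KL}(P, U)/\log N \in [0, 1]$ with $0\log 0 = 0$; empty
bins contribute zero. MI is invariant to amplitude scaling and to phase
rotations by whole bins.

`comodulogram_z()` standardizes MI against surrogates that re-pair each
epoch's amplitude series with a randomly chosen epoch's phase series
(within condition), repeated `n_surr` times (default 1000):
$\mathrm{MI}_Z = (\mathrm{MI}_{obs} - \bar{\mathrm{MI}}_{surr}) /
s_{surr}$, per frequency pair, with zero-SD cells flagged. Phase and
amplitude both come from the Morlet transform (shared wave number), and —
critically — from *buffered* epochs: binning edge-contaminated wavelet
estimates inflates MI_Z by about one SD under the null (the package's
validation isolated this empirically), while interior-only binning with
the 1250 ms buffer yields mean MI_Z ≈ 0 and a ~3.5% two-sided 1.96
exceedance rate. Surrogate SD is computed per frequency pair.

Trial-level MI_Z (`trial_mi_z()`) standardizes each epoch's MI against
surrogates that substitute that epoch's phase with another epoch's phase —
the granularity used for the waveform-confound regressions.

Waveform features per fixation (`waveform_features()`): the epoch is
band-passed (4th-order Butterworth, zero-phase, 1–10 Hz), the Hilbert
transform provides analytic amplitude and event phase, peak and trough
sharpness are the mean absolute amplitude change 2 ms before and after
each extremum (exactly one sample at 500 Hz), and asymmetry — which the
field does not define uniformly — is taken as the log ratio of mean rise
time (trough→peak) to mean decay time (peak→trough). Event-phase
deviations from the condition's circular mean enter regressions as sine
and cosine components. `adjust_pac_for_waveform()` fits one linear model
per feature set plus a Full model, reports each F-test, drops degenerate
regressors with a warning, and returns the Full-model residuals as
adjusted MI_Z (orthogonal to every retained regressor by construction).

## Cluster permutation inference

`cluster_permutation_test()` takes paired per-unit (subject or electrode)
maps, uses the mean within-unit difference per bin as the statistic, and
builds the null by flipping condition labels within units — observations
are never exchanged across units. Per-bin cluster-forming thresholds are
the null's 95th percentile (one-tailed; 2.5th/97.5th two-tailed), clusters
are 4-connected in frequency × time (2-connected along a 1-D axis), and
each observed cluster's summed statistic is referred to the max-cluster-
mass null distribution.

With few units the sign-flip group is tiny ($2^5 = 32$ for five subjects),
and *sampled* permutations make the per-bin threshold estimate jump
stochastically between the largest and second-largest group atoms —
which fragments genuinely supported clusters. The test therefore
enumerates the complete group whenever $2^n \le$ `n_perm` and reports
exact permutation proportions (no add-one correction); this restored both
FWE calibration (3.3% empirical at nominal 5%) and effect localization
(≥ 99% cluster overlap with an injected 0.2 ITC difference).

## Group-level session analysis

`run_session()` executes four standard contrasts: retrieval (original vs
updated fixations on Mismatch trials, pre-fixation map window −750 to
50 ms), associative novelty (updated/Mismatch vs repeated/Match, remembered
trials only, post-fixation window −50 to 750 ms), the peak-vs-trough phase
comparison (pre-window −420 to −380 ms vs post-window 80 to 120 ms at
5 Hz, Watson–Williams with permutation), and the PAC contrast
(updated/Mismatch vs repeated/Match comodulograms). The window
restrictions mirror the scientific questions (retrieval concerns the
moments *leading up to* a fixation; novelty the moments after one) and are
required for a one-tailed contrast to be meaningful when both classes are
phase-locked, just at different latencies.

Session-level flags apply a Bonferroni correction across the four
contrasts, so the probability of any false flag on a no-effect session is
held near 5%. A corrected cluster threshold of 0.05/4 lies below the
$2^{-5}$ p-value floor of a five-subject sign-flip null, so the package's
validation sessions use seven subjects ($2^{-7} = 0.008$) at 180 s each —
the smallest configuration in which corrected cluster flags are
attainable and every memory-filtered fixation class stays populated with
high probability. Validation problem sizes throughout (epoch counts,
permutation counts, session durations) were chosen once as the smallest
configurations at which the corresponding statistics are stable.

## Numerical choices and edge cases

* Seeds: a single integer seed drives every stochastic step; stage seeds
  derive from it via a fixed integer hash, and identical seeds produce
  byte-identical datasets and reports.
* Degenerate inputs are first-class: all-dropout gaze parses to one blink;
  all-zero amplitude is an error for MI; zero-SD surrogate cells, zero-
  resultant circular CIs and constant regressors are flagged rather than
  silently propagated; epochs whose buffered window leaves the recording
  are dropped with a reason.
* Ties: ROI assignment breaks exact distance ties by a fixed ordering;
  theta-frequency selection breaks MI_Z magnitude ties toward the lowest
  frequency.
* The notch filter's stop-band half-width defaults to 2 Hz (the filter
  family, but not the width, is conventionally specified); harmonics are
  optional. Resampling uses a zero-phase FIR anti-alias low-pass, because
  phase distortion would corrupt ITC directly.

## Known limitations

Single-channel simulation (bipolar referencing is exercised on constructed
multi-channel inputs, not on simulated volume-conducted data); no
interictal artifact model (electrode exclusion is a flag, not a detector);
the ERP phase-reset permutation loses power when consecutive fixations
fall inside each other's windows (the clean-window filters exist for
exactly this reason); and the oscillation-presence test assumes the
background is power-law over the 8–60 Hz fit range.
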