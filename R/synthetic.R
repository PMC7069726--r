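# Joint LFP + gaze + trial-structure simulator with known ground truth.
#
# The generated field potential is a sum of three components:
#   * a 1/f aperiodic background, P(f) = 10^offset * f^(-chi), synthesized in
#     the frequency domain with random phases;
#   * a theta oscillation theta_amp * cos(theta(t)) whose instantaneous
#     frequency wanders around theta_freq (Ornstein-Uhlenbeck drift), so that
#     phase-locking to an event decays with distance from the event;
#   * a gamma carrier whose instantaneous amplitude follows the normalized
#     cosine law A_g * (1 + d*cos(theta(t) - phi_c)) / (1 + d), so that
#     coupling_depth d = 1 silences gamma at the anti-preferred phase.
#
# Phase convention: 0 = theta peak, +/-pi = trough.

#' Simulation configuration
#'
#' Builds and validates the configuration for the joint LFP + gaze simulator.
#' Condition-dependent fields (`kappa_by_condition`,
#' `preferred_phase_by_condition`, `coupling_depth_by_condition`,
#' `lock_offset_ms_by_condition`) are named vectors whose names are either a
#' condition (`"Mismatch"`) or a condition/ROI class (`"Mismatch/original"`);
#' the more specific key wins.
#'
#' @param duration_s total recording duration (seconds).
#' @param fs sampling rate (Hz); must exceed `2 * gamma_freq`.
#' @param aperiodic_offset log10-power offset of the 1/f background.
#' @param aperiodic_exponent spectral exponent chi in P(f) ~ f^(-chi).
#' @param theta_freq theta center frequency (Hz).
#' @param theta_freq_sd stationary SD of the instantaneous-frequency drift
#'   (Hz); 0 gives a deterministic sinusoid.
#' @param theta_amp theta amplitude (signal units).
#' @param gamma_freq gamma carrier frequency (Hz).
#' @param gamma_amp gamma carrier amplitude (signal units).
#' @param coupling_phase theta phase of maximal gamma amplitude (radians;
#'   0 = peak, +/-pi = trough).
#' @param coupling_depth modulation depth in \[0, 1\].
#' @param coupling_depth_by_condition optional named override of
#'   `coupling_depth` per condition or condition/ROI class.
#' @param n_trials number of equal-length trials tiling the recording.
#' @param fixation_rate mean fixation rate (Hz).
#' @param kappa_by_condition von Mises concentration of fixation-onset phase
#'   locking, per condition (or condition/ROI class).
#' @param preferred_phase_by_condition preferred theta phase of fixation
#'   onsets, per condition (radians).
#' @param lock_offset_ms_by_condition time offset (ms) of the phase-locked
#'   instant relative to fixation onset (negative = the locked phase occurs
#'   before the fixation).
#' @param p_remember probability a trial is later remembered.
#' @param blink_rate blink rate (Hz) in the generated gaze stream.
#' @param seed integer seed; all randomness derives from it.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(duration_s = 60, fs = 500,
                       aperiodic_offset = 0, aperiodic_exponent = 1.5,
                       theta_freq = 5, theta_freq_sd = 0.8, theta_amp = 1,
                       gamma_freq = 90, gamma_amp = 0.25,
                       coupling_phase = 0, coupling_depth = 0,
                       coupling_depth_by_condition = NULL,
                       n_trials = 10, fixation_rate = 3,
                       kappa_by_condition = c(Match = 0, Mismatch = 0),
                       preferred_phase_by_condition = c(Match = 0, Mismatch = 0),
                       lock_offset_ms_by_condition = NULL,
                       p_remember = 0.72, blink_rate = 0.05, seed = 1) {
  cfg <- list(duration_s = duration_s, fs = fs,
              aperiodic_offset = aperiodic_offset,
              aperiodic_exponent = aperiodic_exponent,
              theta_freq = theta_freq, theta_freq_sd = theta_freq_sd,
              theta_amp = theta_amp, gamma_freq = gamma_freq,
              gamma_amp = gamma_amp, coupling_phase = coupling_phase,
              coupling_depth = coupling_depth,
              coupling_depth_by_condition = coupling_depth_by_condition,
              n_trials = n_trials, fixation_rate = fixation_rate,
              kappa_by_condition = kappa_by_condition,
              preferred_phase_by_condition = preferred_phase_by_condition,
              lock_offset_ms_by_condition = lock_offset_ms_by_condition,
              p_remember = p_remember, blink_rate = blink_rate,
              seed = as.integer(seed))
  check(fs > 2 * gamma_freq, "fs must exceed 2 * gamma_freq")
  check(coupling_depth >= 0 && coupling_depth <= 1,
        "coupling_depth must be in [0, 1]")
  check(all(kappa_by_condition >= 0), "kappa must be >= 0")
  check(p_remember >= 0 && p_remember <= 1, "p_remember must be in [0, 1]")
  check(duration_s > 0 && n_trials >= 1, "need positive duration and trials")
  class(cfg) <- "sim_config"
  cfg
}

# Look up a condition-dependent parameter: "cond/roi" key wins over "cond",
# which wins over the scalar default.
class_param <- function(map, condition, roi, default) {
  if (is.null(map)) return(default)
  key <- paste(condition, roi, sep = "/")
  if (!is.null(names(map)) && key %in% names(map)) return(unname(map[[key]]))
  if (!is.null(names(map)) && condition %in% names(map)) {
    return(unname(map[[condition]]))
  }
  default
}

# 1/f background with exact power-law spectrum (frequency-domain synthesis).
synth_aperiodic <- function(n, fs, offset, exponent) {
  freqs <- seq(0, fs / 2, by = fs / n)
  nf <- length(freqs)
  amp <- numeric(nf)
  # scaled so the one-sided PSD of the output is 10^offset * f^(-exponent);
  # complex-Gaussian coefficients give a true Gaussian process (fixed-modulus
  # random-phase noise has higher-order dependencies that bias
  # phase-amplitude statistics)
  amp[-1] <- sqrt(10^offset * freqs[-1]^(-exponent) * fs / 2)
  half <- amp * (stats::rnorm(nf) + 1i * stats::rnorm(nf)) / sqrt(2)
  half[1] <- 0
  if (n %% 2 == 0) half[nf] <- Re(half[nf])
  spec <- c(half, Conj(rev(half[2:(nf - 1 + n %% 2)])))
  x <- Re(stats::fft(spec, inverse = TRUE)) / sqrt(n)
  x[seq_len(n)]
}

# Trial table tiling the recording: alternating Match/Mismatch in a seeded
# random order, memory labels Bernoulli(p_remember).
make_trials <- function(cfg) {
  len <- cfg$duration_s * 1000 / cfg$n_trials
  onset <- (seq_len(cfg$n_trials) - 1) * len
  cond <- rep(c("Match", "Mismatch"), length.out = cfg$n_trials)
  cond <- sample(cond)
  memory <- ifelse(stats::runif(cfg$n_trials) < cfg$p_remember,
                   "remembered", "forgotten")
  data.frame(trial = seq_len(cfg$n_trials), onset_ms = onset,
             offset_ms = onset + len, condition = cond, memory = memory,
             stringsAsFactors = FALSE)
}

# Fixed on-screen ROI geometry (degrees of visual angle), well separated.
roi_geometry <- function() {
  data.frame(roi = c("original", "updated", "repeated", "other"),
             x = c(-9, 9, 0, 0), y = c(0, 0, 9, -9),
             stringsAsFactors = FALSE)
}

#' Simulate a continuous LFP with known theta phase and coupling
#'
#' @param cfg a [sim_config()] object.
#' @return list with `recording` (list: `signal` channels x samples matrix,
#'   `fs`, `labels`, `exclude`) and `truth` (list: `theta_phase` radians per
#'   sample, `trials` table, coupling ground truth, config echo).
#' @export
simulate_lfp <- function(cfg) {
  check(inherits(cfg, "sim_config"), "cfg must come from sim_config()")
  set.seed(derive_seed(cfg$seed, 1L))
  n <- round(cfg$duration_s * cfg$fs)
  dt <- 1 / cfg$fs
  trials <- make_trials(cfg)

  # instantaneous theta frequency: OU drift around theta_freq
  if (cfg$theta_freq_sd > 0) {
    tau <- 0.3
    a <- exp(-dt / tau)
    innov <- stats::rnorm(n, 0, cfg$theta_freq_sd * sqrt(1 - a^2))
    d <- numeric(n)
    d[1] <- stats::rnorm(1, 0, cfg$theta_freq_sd)
    for (k in 2:n) d[k] <- a * d[k - 1] + innov[k]
    f_inst <- cfg$theta_freq + d
  } else {
    f_inst <- rep(cfg$theta_freq, n)
  }
  theta_phase <- cumsum(2 * pi * f_inst * dt)
  theta_phase <- theta_phase - theta_phase[1] + stats::runif(1, -pi, pi)

  bg <- synth_aperiodic(n, cfg$fs, cfg$aperiodic_offset,
                        cfg$aperiodic_exponent)
  theta <- cfg$theta_amp * cos(theta_phase)

  # per-sample coupling depth (possibly condition-dependent)
  t_ms <- (seq_len(n) - 1) * 1000 / cfg$fs
  depth <- rep(cfg$coupling_depth, n)
  if (!is.null(cfg$coupling_depth_by_condition)) {
    idx <- findInterval(t_ms, trials$onset_ms)
    idx[idx < 1] <- 1
    depth <- vapply(seq_len(nrow(trials)), function(i) {
      class_param(cfg$coupling_depth_by_condition, trials$condition[i], "",
                  cfg$coupling_depth)
    }, numeric(1))[idx]
  }
  gamma_env <- cfg$gamma_amp *
    (1 + depth * cos(theta_phase - cfg$coupling_phase)) / (1 + depth)
  gamma <- gamma_env * cos(2 * pi * cfg$gamma_freq * (t_ms / 1000) +
                             stats::runif(1, 0, 2 * pi))

  sig <- matrix(bg + theta + gamma, nrow = 1)
  rownames(sig) <- "HIPP1"
  recording <- list(signal = sig, fs = cfg$fs, labels = "HIPP1",
                    exclude = stats::setNames(FALSE, "HIPP1"))
  truth <- list(theta_phase = wrap_pi(theta_phase),
                theta_phase_unwrapped = theta_phase,
                true_coupling_phase = cfg$coupling_phase,
                true_coupling_depth = cfg$coupling_depth,
                trials = trials, config = cfg)
  list(recording = recording, truth = truth)
}

#' Simulate a phase-locked fixation event stream
#'
#' Fixation onsets are drawn by thinning a homogeneous Poisson candidate
#' stream: each candidate is accepted with von Mises probability
#' exp(kappa * (cos(theta - mu) - 1)) evaluated at the class's locked instant,
#' and a non-paralyzable minimum spacing enforces fixation durations
#' >= 80 ms. The candidate rate is compensated for both thinning steps so the
#' marginal accepted rate equals `fixation_rate`.
#'
#' @param cfg a [sim_config()] object.
#' @param truth ground truth from [simulate_lfp()].
#' @return event table (data.frame): onset_ms, duration_ms, trial, condition,
#'   roi, memory, x, y; attribute `"phases"` holds the ground-truth locked
#'   phase per fixation.
#' @export
simulate_fixation_stream <- function(cfg, truth) {
  check(all(cfg$kappa_by_condition >= 0), "kappa must be >= 0")
  set.seed(derive_seed(cfg$seed, 2L))
  trials <- truth$trials
  phase_u <- truth$theta_phase_unwrapped
  n <- length(phase_u)
  fs <- cfg$fs
  min_sep_ms <- 115
  sacc_ms <- 30
  geom <- roi_geometry()

  # mean von Mises acceptance over uniform phase is exp(-k) I0(k); the
  # candidate rate is compensated per trial (averaging over that trial's
  # ROI mix) so the accepted rate equals fixation_rate in every condition,
  # plus a non-paralyzable dead-time correction for the minimum spacing.
  roi_for <- function(cond) {
    if (cond == "Mismatch") c("original", "updated") else c("repeated", "other")
  }
  acc_trial <- vapply(seq_len(nrow(trials)), function(i) {
    rois <- roi_for(trials$condition[i])
    mean(vapply(rois, function(r) {
      k <- class_param(cfg$kappa_by_condition, trials$condition[i], r, 0)
      exp(-k) * besselI(k, 0)
    }, numeric(1)))
  }, numeric(1))
  dead <- (min_sep_ms / 1000) * cfg$fixation_rate
  check(dead < 0.9, "fixation_rate too high for the minimum spacing")
  rate_trial <- cfg$fixation_rate / acc_trial / (1 - dead)
  rate_max <- max(rate_trial)

  t_end_ms <- cfg$duration_s * 1000
  onsets <- c(); rois <- c(); phases <- c(); trial_ids <- c()
  t_cur <- stats::rexp(1, rate_max) * 1000
  last_acc <- -Inf
  while (t_cur < t_end_ms - min_sep_ms) {
    tr <- findInterval(t_cur, trials$onset_ms)
    ok_rate <- stats::runif(1) < rate_trial[tr] / rate_max
    if (ok_rate) {
      cond <- trials$condition[tr]
      roi <- sample(roi_for(cond), 1)
      kap <- class_param(cfg$kappa_by_condition, cond, roi, 0)
      mu <- class_param(cfg$preferred_phase_by_condition, cond, roi, 0)
      off_ms <- class_param(cfg$lock_offset_ms_by_condition, cond, roi, 0)
      k_idx <- round((t_cur + off_ms) / 1000 * fs) + 1
      ph <- if (k_idx >= 1 && k_idx <= n) wrap_pi(phase_u[k_idx]) else NA
      ok_vm <- !is.na(ph) && stats::runif(1) < exp(kap * (cos(ph - mu) - 1))
      if (ok_vm && (t_cur - last_acc) >= min_sep_ms) {
        onsets <- c(onsets, t_cur); rois <- c(rois, roi)
        phases <- c(phases, ph); trial_ids <- c(trial_ids, tr)
        last_acc <- t_cur
      }
    }
    t_cur <- t_cur + stats::rexp(1, rate_max) * 1000
  }
  m <- length(onsets)
  check(m >= 1, "no fixations generated; increase duration or rate")
  gaps <- c(diff(onsets), t_end_ms - onsets[m])
  dur <- pmin(80 + stats::rexp(m, 1 / 70), gaps - sacc_ms)
  dur <- pmax(dur, 80)
  ev <- data.frame(onset_ms = onsets, duration_ms = dur,
                   trial = trial_ids,
                   condition = trials$condition[trial_ids],
                   roi = rois, memory = trials$memory[trial_ids],
                   x = geom$x[match(rois, geom$roi)],
                   y = geom$y[match(rois, geom$roi)],
                   stringsAsFactors = FALSE)
  attr(ev, "phases") <- phases
  ev
}

# Raised-cosine position profile for a saccade of given amplitude/duration:
# exceeds the velocity/acceleration detection thresholds for amplitudes
# >= ~0.5 deg at 30 ms duration.
saccade_profile <- function(frac) (1 - cos(pi * frac)) / 2

#' Simulate a 500 Hz gaze-sample stream from an event table
#'
#' Fixations hold position with sub-threshold jitter; the gaps between
#' consecutive fixations are filled with smooth raised-cosine saccades;
#' blinks are emitted as pupil dropouts (pupil = 0) inside long fixations.
#'
#' @param cfg a [sim_config()] object.
#' @param events event table from [simulate_fixation_stream()] (needs
#'   onset_ms, duration_ms, x, y).
#' @return data.frame (time_ms, x_deg, y_deg, pupil) with attribute
#'   `"gaze_truth"`: data.frame of programmed saccade/blink intervals.
#' @export
simulate_gaze <- function(cfg, events) {
  set.seed(derive_seed(cfg$seed, 3L))
  check(all(diff(events$onset_ms) > 0), "events must be time-ordered")
  check(all(events$onset_ms + events$duration_ms <=
              c(events$onset_ms[-1], Inf) + 1e-9),
        "overlapping events")
  fs <- 500
  t_ms <- seq(0, cfg$duration_s * 1000 - 1000 / fs, by = 1000 / fs)
  nsamp <- length(t_ms)
  x <- numeric(nsamp); y <- numeric(nsamp)
  pupil <- 1000 + stats::rnorm(nsamp, 0, 5)
  jit_sd <- 0.02

  ev <- events[order(events$onset_ms), , drop = FALSE]
  m <- nrow(ev)
  # positions before the first fixation: hold the first target
  x[] <- ev$x[1]; y[] <- ev$y[1]
  truth_rows <- list()
  for (i in seq_len(m)) {
    i0 <- findInterval(ev$onset_ms[i], t_ms)
    i1 <- findInterval(ev$onset_ms[i] + ev$duration_ms[i], t_ms)
    i1 <- min(i1, nsamp)
    idx <- i0:i1
    x[idx] <- ev$x[i]; y[idx] <- ev$y[i]
    if (i < m) {
      # gaze holds the old position until a brief (~30 ms) saccade lands on
      # the next fixation target at its onset; a compact saccade keeps peak
      # velocity and acceleration above the detection thresholds
      sacc_ms <- 30
      sac_on <- max(ev$onset_ms[i + 1] - sacc_ms,
                    ev$onset_ms[i] + ev$duration_ms[i])
      s0 <- max(findInterval(sac_on, t_ms) + 1L, i1 + 1L)
      s1 <- findInterval(ev$onset_ms[i + 1], t_ms)
      if (i1 + 1L <= s0 - 1L) {
        x[(i1 + 1L):(s0 - 1L)] <- ev$x[i]
        y[(i1 + 1L):(s0 - 1L)] <- ev$y[i]
      }
      if (s1 >= s0) {
        frac <- seq_along(s0:s1) / (length(s0:s1) + 1)
        prof <- saccade_profile(frac)
        x[s0:s1] <- ev$x[i] + (ev$x[i + 1] - ev$x[i]) * prof
        y[s0:s1] <- ev$y[i] + (ev$y[i + 1] - ev$y[i]) * prof
        amp <- sqrt((ev$x[i + 1] - ev$x[i])^2 + (ev$y[i + 1] - ev$y[i])^2)
        truth_rows[[length(truth_rows) + 1]] <-
          data.frame(kind = "saccade", onset_ms = t_ms[s0], offset_ms = t_ms[s1],
                     amplitude = amp)
      }
      if (s1 < nsamp) {
        x[(s1 + 1):nsamp] <- ev$x[i + 1]; y[(s1 + 1):nsamp] <- ev$y[i + 1]
      }
    }
  }
  # fixation jitter everywhere (sub-threshold by construction)
  x <- x + stats::rnorm(nsamp, 0, jit_sd)
  y <- y + stats::rnorm(nsamp, 0, jit_sd)

  # blinks: Poisson count, placed inside fixations longer than 300 ms
  n_blink <- stats::rpois(1, cfg$blink_rate * cfg$duration_s)
  long_fix <- which(ev$duration_ms > 300)
  if (n_blink > 0 && length(long_fix) > 0) {
    host <- sample(rep(long_fix, 2), min(n_blink, length(long_fix)))
    for (h in unique(host)) {
      b0 <- ev$onset_ms[h] + ev$duration_ms[h] / 2 - 60
      b1 <- b0 + 120
      idx <- which(t_ms >= b0 & t_ms <= b1)
      pupil[idx] <- 0
      truth_rows[[length(truth_rows) + 1]] <-
        data.frame(kind = "blink", onset_ms = b0, offset_ms = b1,
                   amplitude = NA_real_)
    }
  }
  out <- data.frame(time_ms = t_ms, x_deg = x, y_deg = y, pupil = pupil)
  gt <- if (length(truth_rows)) do.call(rbind, truth_rows) else
    data.frame(kind = character(), onset_ms = numeric(),
               offset_ms = numeric(), amplitude = numeric())
  attr(out, "gaze_truth") <- gt
  out
}

#' Write a complete synthetic session to disk
#'
#' Emits plain-text containers: `signal.tsv` (one column per channel),
#' `meta.json` (fs, labels, exclusion flags, seed), `gaze.tsv`, `events.tsv`,
#' `trials.tsv` and `truth.json`. Floating-point fields are written with 12
#' significant digits, so a write-read round trip agrees to better than 1e-9
#' relative error; integer fields round-trip exactly. The same seed produces
#' byte-identical files.
#'
#' @param cfg a [sim_config()] object.
#' @param out_dir output directory (created if missing).
#' @return invisibly, the list of file paths written.
#' @export
make_dataset <- function(cfg, out_dir) {
  sim <- simulate_lfp(cfg)
  ev <- simulate_fixation_stream(cfg, sim$truth)
  gaze <- simulate_gaze(cfg, ev)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  check(dir.exists(out_dir), paste("cannot create", out_dir))
  fmt <- function(df) {
    for (c in names(df)) if (is.numeric(df[[c]]) && !is.integer(df[[c]]))
      df[[c]] <- sprintf("%.12g", df[[c]])
    df
  }
  p_sig <- file.path(out_dir, "signal.tsv")
  sigdf <- as.data.frame(t(sim$recording$signal))
  names(sigdf) <- sim$recording$labels
  utils::write.table(fmt(sigdf), p_sig, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  p_meta <- file.path(out_dir, "meta.json")
  jsonlite::write_json(list(fs = sim$recording$fs,
                            labels = as.list(sim$recording$labels),
                            exclude = as.list(sim$recording$exclude),
                            seed = cfg$seed, duration_s = cfg$duration_s),
                       p_meta, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  p_gaze <- file.path(out_dir, "gaze.tsv")
  utils::write.table(fmt(gaze), p_gaze, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  p_ev <- file.path(out_dir, "events.tsv")
  utils::write.table(fmt(ev), p_ev, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  p_tr <- file.path(out_dir, "trials.tsv")
  utils::write.table(fmt(sim$truth$trials), p_tr, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  p_truth <- file.path(out_dir, "truth.json")
  jsonlite::write_json(list(true_coupling_phase = cfg$coupling_phase,
                            true_coupling_depth = cfg$coupling_depth,
                            theta_freq = cfg$theta_freq,
                            fixation_phases = attr(ev, "phases"),
                            gaze_truth = attr(gaze, "gaze_truth"),
                            seed = cfg$seed),
                       p_truth, auto_unbox = TRUE, digits = 12, pretty = TRUE)
  invisible(list(signal = p_sig, meta = p_meta, gaze = p_gaze,
                 events = p_ev, trials = p_tr, truth = p_truth))
}

#' Read a synthetic session written by [make_dataset()]
#' @param dir dataset directory.
#' @return list with `recording`, `gaze`, `events`, `trials`, `truth`.
#' @export
read_dataset <- function(dir) {
  check(dir.exists(dir), paste("no such dataset directory:", dir))
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  sigdf <- utils::read.table(file.path(dir, "signal.tsv"), header = TRUE,
                             sep = "\t", check.names = FALSE)
  sig <- t(as.matrix(sigdf))
  rownames(sig) <- meta$labels
  recording <- list(signal = sig, fs = meta$fs, labels = meta$labels,
                    exclude = unlist(meta$exclude))
  list(recording = recording,
       gaze = utils::read.table(file.path(dir, "gaze.tsv"), header = TRUE,
                                sep = "\t"),
       events = utils::read.table(file.path(dir, "events.tsv"), header = TRUE,
                                  sep = "\t", stringsAsFactors = FALSE),
       trials = utils::read.table(file.path(dir, "trials.tsv"), header = TRUE,
                                  sep = "\t", stringsAsFactors = FALSE),
       truth = jsonlite::read_json(file.path(dir, "truth.json"),
                                   simplifyVector = TRUE))
}
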