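# Theta-gamma phase-amplitude coupling. MI = D_KL(P, U) / log(N): the
# KL-distance of the phase-binned normalized amplitude distribution P from
# uniform U over N bins, bounded in [0, 1]. MI_Z standardizes MI against a
# surrogate distribution built by permuting the phase time series across
# epochs (within condition), removing bias from non-stationarities and
# event-evoked dynamics.

phase_bins <- function(phase, n_bins = 20) {
  b <- floor((wrap_pi(phase) + pi) / (2 * pi / n_bins)) + 1L
  b[b > n_bins] <- n_bins
  b
}

#' Modulation index of a phase/amplitude pair
#'
#' Amplitudes are binned by phase (default 20 bins of 18 degrees), bin means
#' are normalized to a distribution P, and MI = sum(P log(P/U)) / log(N)
#' with the 0 log 0 = 0 convention; empty bins contribute 0.
#'
#' @param phase phase series (radians).
#' @param amplitude amplitude series (>= 0, not all zero), same length.
#' @param n_bins number of phase bins (default 20).
#' @return list of class `amplitude_by_phase`: `mi`, `p` (normalized mean
#'   amplitude per bin), `counts`, `edges` (bin edges, radians).
#' @export
modulation_index <- function(phase, amplitude, n_bins = 20) {
  check(length(phase) == length(amplitude), "series must be equal length")
  check(all(amplitude >= 0), "amplitude must be non-negative")
  check(any(amplitude > 0), "amplitude must not be all zero")
  b <- phase_bins(phase, n_bins)
  sums <- numeric(n_bins)
  agg <- rowsum(amplitude, b)
  sums[as.integer(rownames(agg))] <- agg[, 1]
  counts <- tabulate(b, n_bins)
  means <- ifelse(counts > 0, sums / pmax(counts, 1), 0)
  p <- means / sum(means)
  nz <- p > 0
  dkl <- sum(p[nz] * log(p[nz] * n_bins))
  structure(list(mi = dkl / log(n_bins), p = p, counts = counts,
                 edges = seq(-pi, pi, length.out = n_bins + 1)),
            class = "amplitude_by_phase")
}

# MI values for every amplitude-frequency column at once, from bin-summed
# amplitudes. sums: n_bins x n_af; counts: length n_bins.
mi_from_sums <- function(sums, counts, n_bins) {
  means <- sums / pmax(counts, 1)
  means[counts == 0, ] <- 0
  tot <- colSums(means)
  apply(means, 2, function(m) {
    s <- sum(m)
    if (s <= 0) return(NA_real_)
    p <- m / s
    nz <- p > 0
    sum(p[nz] * log(p[nz] * n_bins)) / log(n_bins)
  })
}

#' Surrogate-normalized comodulogram
#'
#' Phase (1-10 Hz) and amplitude (80-200 Hz) series are extracted per epoch
#' with the Morlet transform (shared wave number, so phase and amplitude
#' estimators are consistent). The observed MI per frequency pair is
#' computed over all epochs concatenated; each surrogate re-pairs every
#' amplitude epoch with a randomly permuted phase epoch before
#' concatenation. MI_Z = (MI_obs - mean(surrogate)) / sd(surrogate), per
#' frequency pair; cells with zero surrogate SD are flagged NA.
#'
#' @param epochs an `epoch_set` (buffered; phase/amplitude are estimated on
#'   the buffered epoch and MI evaluated on the analysis window only), or a
#'   numeric matrix epochs x samples with `fs` and `buffer_ms` supplied.
#' @param fs sampling rate (matrix input).
#' @param buffer_ms for matrix input: margin on each side of every epoch
#'   that is transformed but excluded from MI binning, protecting against
#'   wavelet edge artifacts (which otherwise bias MI_Z upward).
#' @param phase_freqs slow frequencies (Hz).
#' @param amp_freqs fast frequencies (Hz).
#' @param n_surr surrogate permutations (default 1000).
#' @param n_bins phase bins.
#' @param wave_number Morlet wave number.
#' @param seed RNG seed.
#' @return list of class `comodulogram`: `mi_z`, `mi_obs` (phase-freqs x
#'   amp-freqs), `phase_freqs`, `amp_freqs`, `n_surr`, `n_epochs`.
#' @export
comodulogram_z <- function(epochs, fs = NULL, buffer_ms = 0,
                           phase_freqs = log_freqs(10, 1, 10),
                           amp_freqs = log_freqs(13, 80, 200),
                           n_surr = 1000, n_bins = 20, wave_number = 5,
                           seed = 1) {
  if (inherits(epochs, "epoch_set")) {
    tf_p <- morlet_transform(epochs, phase_freqs, wave_number)
    tf_a <- morlet_transform(epochs, amp_freqs, wave_number)
  } else {
    epochs <- as.matrix(epochs)
    check(!is.null(fs), "fs required for matrix input")
    tf_p <- morlet_transform(epochs, phase_freqs, wave_number, fs = fs)
    tf_a <- morlet_transform(epochs, amp_freqs, wave_number, fs = fs)
    if (buffer_ms > 0) {
      nb <- round(buffer_ms / 1000 * fs)
      keep <- (nb + 1):(dim(tf_p$phase)[3] - nb)
      check(length(keep) >= 100, "buffer leaves too few samples")
      tf_p$phase <- tf_p$phase[, , keep, drop = FALSE]
      tf_a$power <- tf_a$power[, , keep, drop = FALSE]
    }
  }
  n_ep <- dim(tf_p$phase)[1]
  check(n_ep >= 2, "need at least 2 epochs")
  L <- dim(tf_p$phase)[3]
  n_pf <- length(phase_freqs); n_af <- length(amp_freqs)

  # A_big: (L * n_ep) x n_af, rows grouped by epoch then time
  A_big <- matrix(0, L * n_ep, n_af)
  for (j in seq_len(n_af)) {
    A_big[, j] <- as.vector(t(sqrt(tf_a$power[, j, ])))
  }
  # bins_mats[[pf]]: L x n_ep matrix of phase-bin labels
  bins_mats <- lapply(seq_len(n_pf), function(j) {
    matrix(phase_bins(as.vector(t(tf_p$phase[, j, ])), n_bins), L, n_ep)
  })

  mi_for <- function(ord) {
    out <- matrix(NA_real_, n_pf, n_af)
    for (j in seq_len(n_pf)) {
      bins_vec <- as.vector(bins_mats[[j]][, ord])
      counts <- tabulate(bins_vec, n_bins)
      agg <- rowsum(A_big, bins_vec)
      sums <- matrix(0, n_bins, n_af)
      sums[as.integer(rownames(agg)), ] <- agg
      out[j, ] <- mi_from_sums(sums, counts, n_bins)
    }
    out
  }

  mi_obs <- mi_for(seq_len(n_ep))
  set.seed(seed)
  surr_sum <- matrix(0, n_pf, n_af)
  surr_sq <- matrix(0, n_pf, n_af)
  for (s in seq_len(n_surr)) {
    m <- mi_for(sample.int(n_ep))
    surr_sum <- surr_sum + m
    surr_sq <- surr_sq + m^2
  }
  mu <- surr_sum / n_surr
  sdv <- sqrt(pmax(surr_sq / n_surr - mu^2, 0) * n_surr / (n_surr - 1))
  mi_z <- (mi_obs - mu) / sdv
  mi_z[sdv == 0] <- NA_real_
  structure(list(mi_z = mi_z, mi_obs = mi_obs, phase_freqs = phase_freqs,
                 amp_freqs = amp_freqs, n_surr = n_surr, n_epochs = n_ep),
            class = "comodulogram")
}

#' Trial-level surrogate-normalized MI at one frequency pair
#'
#' Per-epoch MI_Z: each epoch's observed MI is standardized against
#' surrogates that substitute that epoch's phase series with another
#' (randomly chosen) epoch's phase series.
#'
#' @param epochs matrix epochs x samples.
#' @param fs sampling rate.
#' @param phase_freq,amp_freq frequency pair (Hz).
#' @param buffer_ms margin transformed but excluded from binning (edge
#'   protection), per side.
#' @param n_surr surrogates per epoch (default 100).
#' @param n_bins phase bins.
#' @param wave_number Morlet wave number.
#' @param seed RNG seed.
#' @return numeric vector of per-epoch MI_Z.
#' @export
trial_mi_z <- function(epochs, fs, phase_freq, amp_freq, buffer_ms = 0,
                       n_surr = 100, n_bins = 20, wave_number = 5,
                       seed = 1) {
  epochs <- as.matrix(epochs)
  n_ep <- nrow(epochs)
  check(n_ep >= 10, "need at least 10 epochs")
  tf_p <- morlet_transform(epochs, phase_freq, wave_number, fs = fs)
  tf_a <- morlet_transform(epochs, amp_freq, wave_number, fs = fs)
  if (buffer_ms > 0) {
    nb <- round(buffer_ms / 1000 * fs)
    keep <- (nb + 1):(dim(tf_p$phase)[3] - nb)
    tf_p$phase <- tf_p$phase[, , keep, drop = FALSE]
    tf_a$power <- tf_a$power[, , keep, drop = FALSE]
  }
  L <- dim(tf_p$phase)[3]
  B <- matrix(phase_bins(as.vector(tf_p$phase[, 1, ]), n_bins), n_ep, L)
  A <- matrix(sqrt(as.vector(tf_a$power[, 1, ])), n_ep, L)
  mi_one <- function(b, a) {
    counts <- tabulate(b, n_bins)
    sums <- numeric(n_bins)
    agg <- rowsum(a, b)
    sums[as.integer(rownames(agg))] <- agg[, 1]
    mi_from_sums(matrix(sums, ncol = 1), counts, n_bins)[1]
  }
  set.seed(seed)
  vapply(seq_len(n_ep), function(k) {
    obs <- mi_one(B[k, ], A[k, ])
    donors <- sample(setdiff(seq_len(n_ep), k), n_surr, replace = TRUE)
    null <- vapply(donors, function(j) mi_one(B[j, ], A[k, ]), numeric(1))
    s <- stats::sd(null)
    if (s == 0) return(NA_real_)
    (obs - mean(null)) / s
  }, numeric(1))
}

#' Select the dominant theta frequency across comodulograms
#'
#' The phase frequency within `band` with the greatest magnitude MI_Z,
#' pooled (elementwise max of |MI_Z|) across conditions; ties go to the
#' lowest frequency.
#'
#' @param comods list of `comodulogram` objects sharing the frequency grid.
#' @param band phase-frequency band (Hz, default c(4, 6)).
#' @return selected frequency (Hz).
#' @export
select_theta_frequency <- function(comods, band = c(4, 6)) {
  if (inherits(comods, "comodulogram")) comods <- list(comods)
  pf <- comods[[1]]$phase_freqs
  for (cm in comods) check(isTRUE(all.equal(cm$phase_freqs, pf)),
                           "comodulograms must share the frequency grid")
  sel <- which(pf >= band[1] & pf <= band[2])
  check(length(sel) > 0, "band outside the frequency grid")
  pooled <- Reduce(pmax, lapply(comods, function(cm) {
    apply(abs(cm$mi_z), 1, max, na.rm = TRUE)
  }))
  pf[sel[which.max(pooled[sel])]]
}

#' Theta waveform-shape features per epoch
#'
#' The signal is band-pass filtered (4th-order Butterworth, zero-phase) into
#' the theta range, the analytic amplitude and phase come from the Hilbert
#' transform, and cycle landmarks (peaks/troughs) are located at local
#' extrema. Sharpness is the mean absolute change in amplitude 2 ms before
#' and after the extremum; asymmetry is the mean log ratio of rise time
#' (trough to peak) to decay time (peak to trough).
#'
#' @param epochs matrix epochs x samples.
#' @param fs sampling rate (Hz).
#' @param band filter band (Hz, default c(1, 10)).
#' @param event_idx sample index of the time-locking event within the epoch
#'   (default: middle sample); the analytic phase there is returned.
#' @return data.frame per epoch: power (mean squared analytic amplitude),
#'   amp (mean analytic amplitude), phase_event (radians), s_peak, s_trough,
#'   asym.
#' @export
waveform_features <- function(epochs, fs, band = c(1, 10),
                              event_idx = NULL) {
  epochs <- as.matrix(epochs)
  n <- ncol(epochs)
  if (is.null(event_idx)) event_idx <- floor(n / 2) + 1
  bf <- signal::butter(4, band / (fs / 2), type = "pass")
  koff <- max(1L, round(0.002 * fs))
  out <- lapply(seq_len(nrow(epochs)), function(e) {
    xf <- signal::filtfilt(bf, epochs[e, ])
    an <- analytic_signal(xf)
    amp <- Mod(an)
    dxs <- diff(xf)
    pk <- which(dxs[-length(dxs)] > 0 & dxs[-1] <= 0) + 1L
    tr <- which(dxs[-length(dxs)] < 0 & dxs[-1] >= 0) + 1L
    pk <- pk[pk > koff & pk <= n - koff]
    tr <- tr[tr > koff & tr <= n - koff]
    check(length(pk) > 0 && length(tr) > 0, "no extrema found")
    sharp <- function(ix) mean((abs(xf[ix] - xf[ix - koff]) +
                                  abs(xf[ix] - xf[ix + koff])) / 2)
    # rise/decay per cycle: trough -> next peak -> next trough
    ext <- sort(c(pk, tr))
    is_pk <- ext %in% pk
    rises <- c(); decays <- c()
    for (i in seq_len(length(ext) - 1)) {
      dtt <- ext[i + 1] - ext[i]
      if (!is_pk[i] && is_pk[i + 1]) rises <- c(rises, dtt)
      if (is_pk[i] && !is_pk[i + 1]) decays <- c(decays, dtt)
    }
    asym <- if (length(rises) && length(decays)) {
      log(mean(rises) / mean(decays))
    } else 0
    data.frame(power = mean(amp^2), amp = mean(amp),
               phase_event = Arg(an[event_idx]),
               s_peak = sharp(pk), s_trough = sharp(tr), asym = asym)
  })
  do.call(rbind, out)
}

#' Add phase-locking components to a feature table
#'
#' The single-trial phase-locking measure is the deviation of each epoch's
#' event phase from the circular mean event phase of its condition,
#' linearized as sine and cosine components for regression.
#'
#' @param features output of [waveform_features()].
#' @param condition per-epoch condition labels.
#' @return `features` with `sin_theta` and `cos_theta` columns added.
#' @export
add_phase_deviation <- function(features, condition) {
  dev <- numeric(nrow(features))
  for (cond in unique(condition)) {
    idx <- condition == cond
    mu <- circ_mean(features$phase_event[idx])$mean
    dev[idx] <- wrap_pi(features$phase_event[idx] - mu)
  }
  features$sin_theta <- sin(dev)
  features$cos_theta <- cos(dev)
  features
}

#' Regression-based waveform confound control for PAC
#'
#' Fits one linear model of trial-level MI_Z per feature set (Power, Sin,
#' Cos, S_peak, S_trough, Asym, and the Full model with all features),
#' reports each model's F-test, and returns adjusted MI_Z as the residuals
#' of the Full model (independent of every retained regressor by
#' construction). Constant or collinear regressors are dropped with a
#' warning.
#'
#' @param mi_z numeric vector of trial-level MI_Z (n >= 10).
#' @param features data.frame with columns power, sin_theta, cos_theta,
#'   s_peak, s_trough, asym (extra columns ignored).
#' @param model_sets named list of character vectors of feature columns; the
#'   default mirrors the standard single-feature + Full layout.
#' @return list of class `adjusted_pac`: `adjusted` (residuals of the Full
#'   model), `raw`, `report` (data.frame: set, F, df1, df2, p), `dropped`.
#' @export
adjust_pac_for_waveform <- function(mi_z, features, model_sets = NULL) {
  check(length(mi_z) >= 10, "need at least 10 trials")
  check(all(is.finite(mi_z)), "mi_z must be finite")
  feats <- c("power", "sin_theta", "cos_theta", "s_peak", "s_trough", "asym")
  feats <- feats[feats %in% names(features)]
  if (is.null(model_sets)) {
    model_sets <- c(stats::setNames(as.list(feats),
                                    c("Power", "Sin", "Cos", "S_peak",
                                      "S_trough", "Asym")[seq_along(feats)]),
                    list(Full = feats))
  }
  X <- features[, feats, drop = FALSE]
  dropped <- character(0)
  for (f in feats) {
    if (stats::sd(X[[f]]) < 1e-12 || !all(is.finite(X[[f]]))) {
      dropped <- c(dropped, f)
    }
  }
  if (length(dropped)) {
    warning("dropping degenerate regressors: ",
            paste(dropped, collapse = ", "))
  }
  keep <- setdiff(feats, dropped)
  report <- list()
  full_fit <- NULL
  for (nm in names(model_sets)) {
    vars <- intersect(model_sets[[nm]], keep)
    if (!length(vars)) next
    dat <- cbind(data.frame(.y = mi_z), X[, vars, drop = FALSE])
    fit <- stats::lm(.y ~ ., data = dat)
    fstat <- summary(fit)$fstatistic
    pv <- if (is.null(fstat)) NA_real_ else
      stats::pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE)
    report[[length(report) + 1]] <-
      data.frame(set = nm, F = if (is.null(fstat)) NA_real_ else fstat[1],
                 df1 = if (is.null(fstat)) NA_real_ else fstat[2],
                 df2 = if (is.null(fstat)) NA_real_ else fstat[3],
                 p = unname(pv), stringsAsFactors = FALSE)
    if (nm == "Full") full_fit <- fit
  }
  check(!is.null(full_fit), "Full model could not be fitted")
  structure(list(adjusted = unname(stats::residuals(full_fit)),
                 raw = mi_z,
                 report = do.call(rbind, report), dropped = dropped),
            class = "adjusted_pac")
}
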