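# iEEG preprocessing: bipolar montage, zero-phase line-noise filtering,
# anti-aliased downsampling, and fixation-locked buffered epoching.

#' Construct a continuous recording object
#' @param signal channels x samples numeric matrix (microvolts).
#' @param fs sampling rate (Hz).
#' @param labels channel labels (unique).
#' @param exclude logical exclusion flags per channel (interictal /
#'   seizure-onset); default all FALSE.
#' @return list of class `continuous_recording`.
#' @export
continuous_recording <- function(signal, fs, labels = rownames(signal),
                                 exclude = NULL) {
  signal <- as.matrix(signal)
  if (is.null(labels)) labels <- paste0("ch", seq_len(nrow(signal)))
  if (is.null(exclude)) exclude <- stats::setNames(rep(FALSE, nrow(signal)),
                                                   labels)
  check(all(is.finite(signal)), "signal must be finite")
  check(fs > 0, "fs must be positive")
  check(!anyDuplicated(labels), "labels must be unique")
  check(length(labels) == nrow(signal), "one label per channel")
  rownames(signal) <- labels
  structure(list(signal = signal, fs = fs, labels = labels,
                 exclude = exclude),
            class = "continuous_recording")
}

as_recording <- function(rec) {
  if (inherits(rec, "continuous_recording")) return(rec)
  continuous_recording(rec$signal, rec$fs, rec$labels, rec$exclude)
}

#' Re-reference to a bipolar montage
#'
#' Each output channel is anode minus cathode for adjacent contact pairs.
#' Exclusion flags propagate: a pair is excluded if either member is.
#'
#' @param rec a recording (list with signal, fs, labels, exclude).
#' @param pairs list of `c(anode, cathode)` label pairs.
#' @return a `continuous_recording` with one channel per pair, labelled
#'   `"anode-cathode"`.
#' @export
bipolar_reference <- function(rec, pairs) {
  rec <- as_recording(rec)
  out <- matrix(0, nrow = length(pairs), ncol = ncol(rec$signal))
  labs <- character(length(pairs))
  excl <- logical(length(pairs))
  for (i in seq_along(pairs)) {
    p <- pairs[[i]]
    check(all(p %in% rec$labels),
          paste("unknown channel label in pair:", paste(p, collapse = ", ")))
    out[i, ] <- rec$signal[p[1], ] - rec$signal[p[2], ]
    labs[i] <- paste(p[1], p[2], sep = "-")
    excl[i] <- isTRUE(rec$exclude[[p[1]]]) || isTRUE(rec$exclude[[p[2]]])
  }
  continuous_recording(out, rec$fs, labs, stats::setNames(excl, labs))
}

#' Zero-phase band-stop line-noise filter
#'
#' Butterworth band-stop centered on `line_freq` applied forward-backward
#' (`signal::filtfilt`), so the net response is zero-phase. Harmonics up to
#' Nyquist are optionally filtered too.
#'
#' @param rec recording.
#' @param line_freq line frequency (Hz), must be below Nyquist.
#' @param order Butterworth design order (default 4).
#' @param width half-width of the stopband (Hz, default 2).
#' @param harmonics filter integer harmonics below Nyquist (default FALSE).
#' @return filtered recording.
#' @export
notch_filter <- function(rec, line_freq, order = 4, width = 2,
                         harmonics = FALSE) {
  rec <- as_recording(rec)
  nyq <- rec$fs / 2
  check(line_freq < nyq, "line_freq must be below Nyquist")
  targets <- if (harmonics) {
    line_freq * seq_len(floor((nyq - width - 0.5) / line_freq))
  } else line_freq
  sig <- rec$signal
  for (f0 in targets) {
    bf <- signal::butter(order, c(f0 - width, f0 + width) / nyq, type = "stop")
    for (ch in seq_len(nrow(sig))) {
      sig[ch, ] <- signal::filtfilt(bf, sig[ch, ])
    }
  }
  continuous_recording(sig, rec$fs, rec$labels, rec$exclude)
}

#' Anti-aliased downsampling
#'
#' Zero-phase FIR anti-alias low-pass (cutoff 0.8 x target Nyquist, applied
#' with `filtfilt`) followed by polyphase index selection. Only downsampling
#' is supported.
#'
#' @param rec recording.
#' @param fs_target target rate (Hz), `<=` current rate.
#' @return resampled recording; output length `round(n * fs_target / fs)`.
#' @export
resample_recording <- function(rec, fs_target = 500) {
  rec <- as_recording(rec)
  check(fs_target <= rec$fs, "upsampling not supported")
  if (fs_target == rec$fs) return(rec)
  n <- ncol(rec$signal)
  n_out <- round(n * fs_target / rec$fs)
  cutoff <- 0.8 * (fs_target / 2) / (rec$fs / 2)
  fir <- signal::fir1(64, cutoff)
  idx <- floor(seq(0, n - 1, by = rec$fs / fs_target))[seq_len(n_out)] + 1
  out <- matrix(0, nrow(rec$signal), n_out)
  for (ch in seq_len(nrow(rec$signal))) {
    low <- signal::filtfilt(fir, rec$signal[ch, ])
    out[ch, ] <- low[idx]
  }
  continuous_recording(out, fs_target, rec$labels, rec$exclude)
}

#' Extract buffered fixation-locked epochs
#'
#' Epochs span `window` around each onset plus a symmetric `buffer` on both
#' sides; the buffer is retained for spectral transforms (edge-artifact
#' protection) and trimmed afterwards. Onsets whose buffered window exits the
#' recording are dropped with a reason recorded in the `dropped` attribute.
#'
#' @param rec recording (single channel used; pass `channel` to select).
#' @param onsets_ms fixation onsets (ms from recording start).
#' @param window c(start, end) ms relative to onset (default c(-750, 750)).
#' @param buffer_ms buffer on each side (default 1250).
#' @param channel channel index or label (default 1).
#' @param metadata optional data.frame of per-onset metadata (carried along,
#'   rows dropped in step with dropped onsets).
#' @return list of class `epoch_set`: `data` epochs x samples, `fs`,
#'   `window`, `buffer_ms`, `times_ms` (per retained sample, relative to
#'   onset, buffered), `metadata`, `onsets_ms`; attribute `dropped`.
#' @export
extract_epochs <- function(rec, onsets_ms, window = c(-750, 750),
                           buffer_ms = 1250, channel = 1,
                           metadata = NULL) {
  rec <- as_recording(rec)
  if (is.character(channel)) channel <- match(channel, rec$labels)
  x <- rec$signal[channel, ]
  fs <- rec$fs
  n <- length(x)
  lo_ms <- window[1] - buffer_ms
  hi_ms <- window[2] + buffer_ms
  i_lo <- round(onsets_ms / 1000 * fs) + round(lo_ms / 1000 * fs)
  i_hi <- round(onsets_ms / 1000 * fs) + round(hi_ms / 1000 * fs)
  keep <- i_lo >= 0 & i_hi <= n - 1
  dropped <- data.frame(onset_ms = onsets_ms[!keep],
                        reason = rep("buffered window outside recording",
                                     sum(!keep)))
  check(any(keep), "zero surviving epochs")
  len <- round(hi_ms / 1000 * fs) - round(lo_ms / 1000 * fs) + 1
  data <- t(vapply(which(keep), function(i) {
    x[(i_lo[i] + 1):(i_lo[i] + len)]
  }, numeric(len)))
  times_ms <- (round(lo_ms / 1000 * fs) + seq_len(len) - 1) * 1000 / fs
  md <- if (!is.null(metadata)) metadata[keep, , drop = FALSE] else NULL
  structure(list(data = data, fs = fs, window = window,
                 buffer_ms = buffer_ms, times_ms = times_ms,
                 metadata = md, onsets_ms = onsets_ms[keep]),
            class = "epoch_set", dropped = dropped)
}

#' Trim the buffer from a time axis mask
#' @param times_ms buffered epoch time axis.
#' @param window analysis window c(start, end) ms.
#' @return logical mask selecting samples inside the window.
#' @export
window_mask <- function(times_ms, window) {
  times_ms >= window[1] & times_ms <= window[2]
}
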