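# Inter-trial phase coherence and the ERP-based phase-reset analysis.
# ITC_ft = (1/N) |sum_k exp(i phi_ftk)|: 1 = perfect phase alignment across
# events, ~0 = uniform phases. ITC is biased upward at small N
# (E[R] ~ sqrt(pi)/(2 sqrt(N)) under uniformity), hence the subsample-matched
# contrast.

#' Inter-trial phase coherence
#'
#' @param phase array of phases: epochs x freqs x time (radians), or an
#'   epochs x time matrix, or a plain vector of phases across epochs.
#' @return list of class `itc_map`: `itc` (freqs x time matrix, or scalar
#'   for vector input), `n_events`.
#' @export
itc <- function(phase) {
  if (is.vector(phase)) {
    check(length(phase) >= 2, "ITC needs at least 2 events")
    return(structure(list(itc = Mod(mean(exp(1i * phase))),
                          n_events = length(phase)), class = "itc_map"))
  }
  if (is.matrix(phase)) phase <- array(phase, c(nrow(phase), 1, ncol(phase)))
  n <- dim(phase)[1]
  check(n >= 2, "ITC needs at least 2 events")
  z <- exp(1i * phase)
  m <- apply(z, c(2, 3), mean)
  structure(list(itc = Mod(m), n_events = n), class = "itc_map")
}

#' Subsample-matched ITC contrast
#'
#' ITC is biased by the number of events, so the larger condition is
#' randomly subsampled to the smaller condition's N; ITC maps are averaged
#' over `n_draws` independent subsamples before differencing.
#'
#' @param phase_a,phase_b phase arrays (epochs x freqs x time), same
#'   freq/time grid.
#' @param n_draws number of random subsamples to average (default 100).
#' @param seed RNG seed.
#' @return list: `itc_a`, `itc_b` (freqs x time, at matched N), `diff`
#'   (A - B), `n_matched`, `n_draws`.
#' @export
itc_contrast_subsampled <- function(phase_a, phase_b, n_draws = 100,
                                    seed = 1) {
  if (is.matrix(phase_a)) phase_a <- array(phase_a, c(nrow(phase_a), 1, ncol(phase_a)))
  if (is.matrix(phase_b)) phase_b <- array(phase_b, c(nrow(phase_b), 1, ncol(phase_b)))
  na <- dim(phase_a)[1]; nb <- dim(phase_b)[1]
  check(na >= 2 && nb >= 2, "both conditions need at least 2 events")
  n <- min(na, nb)
  set.seed(seed)
  sub_itc <- function(ph, n_from) {
    if (n_from == n) return(itc(ph)$itc)
    acc <- 0
    for (d in seq_len(n_draws)) {
      idx <- sample.int(n_from, n)
      acc <- acc + itc(ph[idx, , , drop = FALSE])$itc
    }
    acc / n_draws
  }
  ia <- sub_itc(phase_a, na)
  ib <- sub_itc(phase_b, nb)
  list(itc_a = ia, itc_b = ib, diff = ia - ib, n_matched = n,
       n_draws = n_draws)
}

#' ERP-based phase-reset analysis
#'
#' A phase reset (as opposed to an added evoked response with power change)
#' appears as increased post-fixation power relative to pre-fixation power in
#' the across-events average ERP. The observed statistic per frequency is
#' log(post ERP power / pre ERP power); the null exchanges the pre/post
#' segment assignment per epoch, and the contrast is cluster-corrected over
#' frequency (2-connectivity in the 1-D frequency axis).
#'
#' @param epochs an `epoch_set` (buffered) or matrix with `times_ms`/`fs`.
#' @param pre_window,post_window analysis windows (ms relative to onset);
#'   defaults c(-750, 50) and c(-50, 750).
#' @param freqs frequencies at which segment power is evaluated (Hz).
#' @param n_perm permutations for the cluster test.
#' @param seed RNG seed.
#' @param times_ms,fs needed for matrix input.
#' @return list: `freqs`, `pre_power`, `post_power`, `stat`
#'   (log power ratio per frequency), `clusters` (a `cluster_result`).
#' @export
erp_power_reset <- function(epochs, pre_window = c(-750, 50),
                            post_window = c(-50, 750),
                            freqs = log_freqs(20, 1, 10), n_perm = 500,
                            seed = 1, times_ms = NULL, fs = NULL) {
  if (inherits(epochs, "epoch_set")) {
    data <- epochs$data; times_ms <- epochs$times_ms; fs <- epochs$fs
  } else {
    data <- as.matrix(epochs)
    check(!is.null(times_ms) && !is.null(fs), "times_ms and fs required")
  }
  n_ep <- nrow(data)
  check(n_ep >= 10, "need at least 10 epochs")
  pre_idx <- which(window_mask(times_ms, pre_window))
  post_idx <- which(window_mask(times_ms, post_window))
  check(length(pre_idx) > 0 && length(post_idx) > 0,
        "windows exceed epoch bounds")
  m <- min(length(pre_idx), length(post_idx))
  pre_idx <- pre_idx[seq_len(m)]; post_idx <- post_idx[seq_len(m)]

  seg_power <- function(seg) {
    # ERP of the segment set; multitaper power at the target frequencies
    erp <- colMeans(seg)
    erp <- erp - mean(erp)
    ps <- multitaper_psd(erp, fs, fmin = 0, fmax = fs / 2)
    vapply(freqs, function(f) {
      ps$power[which.min(abs(ps$freqs - f))]
    }, numeric(1))
  }
  pre_seg <- data[, pre_idx, drop = FALSE]
  post_seg <- data[, post_idx, drop = FALSE]
  p_pre <- seg_power(pre_seg)
  p_post <- seg_power(post_seg)
  stat_obs <- log(p_post / pmax(p_pre, .Machine$double.xmin))

  set.seed(seed)
  null_stats <- matrix(0, n_perm, length(freqs))
  for (b in seq_len(n_perm)) {
    flip <- stats::runif(n_ep) < 0.5
    pre_b <- pre_seg; post_b <- post_seg
    pre_b[flip, ] <- post_seg[flip, ]
    post_b[flip, ] <- pre_seg[flip, ]
    null_stats[b, ] <- log(seg_power(post_b) /
                             pmax(seg_power(pre_b), .Machine$double.xmin))
  }
  cl <- cluster_from_null(stat_obs, null_stats, tail = "one")
  list(freqs = freqs, pre_power = p_pre, post_power = p_post,
       stat = stat_obs, clusters = cl)
}
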