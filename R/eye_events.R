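# Gaze parsing and viewing-behavior analysis. Saccades are detected when
# velocity, acceleration and motion thresholds are jointly exceeded
# (0.15 deg, 30 deg/s, 8000 deg/s^2 defaults); blinks come from pupil
# dropouts; every remaining sample is a fixation. Velocity and acceleration
# are estimated by central differences after a 3-sample median filter.

#' Parse gaze samples into fixation, saccade and blink events
#'
#' The output events partition the record: every sample belongs to exactly
#' one event. Fixations shorter than `min_fix_ms` are kept but flagged
#' `excluded`. Samples within `blink_pad_ms` of a pupil dropout are absorbed
#' into the blink (eyelid artifacts corrupt velocity estimates).
#'
#' @param samples data.frame with columns time_ms, x_deg, y_deg, pupil
#'   (pupil <= 0 or NA = no signal); nominal 500 Hz spacing.
#' @param motion minimum displacement for a saccade (degrees).
#' @param velocity velocity threshold (deg/s).
#' @param acceleration acceleration threshold (deg/s^2).
#' @param min_fix_ms minimum fixation duration (ms); shorter ones are
#'   flagged excluded.
#' @param blink_pad_ms padding absorbed into blink events (ms).
#' @return data.frame: kind (fixation/saccade/blink), onset_ms, offset_ms,
#'   x, y (fixations: mean gaze position), excluded (logical).
#' @export
detect_eye_events <- function(samples, motion = 0.15, velocity = 30,
                              acceleration = 8000, min_fix_ms = 80,
                              blink_pad_ms = 25) {
  t <- samples$time_ms
  check(all(diff(t) > 0), "time must be strictly increasing")
  check(t[length(t)] - t[1] >= 100, "need at least 100 ms of samples")
  n <- length(t)
  dt_ms <- stats::median(diff(t))
  x <- samples$x_deg; y <- samples$y_deg
  pupil <- samples$pupil
  blink_raw <- is.na(pupil) | pupil <= 0

  if (all(blink_raw)) {
    return(data.frame(kind = "blink", onset_ms = t[1],
                      offset_ms = t[n] + dt_ms, x = NA_real_, y = NA_real_,
                      excluded = FALSE, stringsAsFactors = FALSE))
  }

  # pad blinks
  blink <- blink_raw
  pad_n <- ceiling(blink_pad_ms / dt_ms)
  if (any(blink_raw) && pad_n > 0) {
    idx <- which(blink_raw)
    for (d in seq_len(pad_n)) {
      blink[pmax(idx - d, 1)] <- TRUE
      blink[pmin(idx + d, n)] <- TRUE
    }
  }

  # velocity/acceleration on median-filtered traces; blink samples excluded
  xm <- stats::runmed(x, 3); ym <- stats::runmed(y, 3)
  dts <- dt_ms / 1000
  cdiff <- function(v) c(v[2] - v[1], (v[3:n] - v[1:(n - 2)]) / 2,
                         v[n] - v[n - 1]) / dts
  vx <- cdiff(xm); vy <- cdiff(ym)
  speed <- sqrt(vx^2 + vy^2)
  ax <- cdiff(vx); ay <- cdiff(vy)
  acc <- sqrt(ax^2 + ay^2)

  sac <- speed > velocity & !blink
  # candidate saccades must also satisfy acceleration and motion thresholds;
  # accepted events are extended to a lower hysteresis threshold so the
  # onset lands at the start of the velocity rise rather than at the main
  # threshold crossing
  lab <- label_components(sac)
  if (any(lab > 0)) {
    for (k in seq_len(max(lab))) {
      idx <- which(lab == k)
      disp <- sqrt((xm[idx[length(idx)]] - xm[idx[1]])^2 +
                     (ym[idx[length(idx)]] - ym[idx[1]])^2)
      if (max(acc[idx]) < acceleration || disp < motion) {
        sac[idx] <- FALSE
      } else {
        hyst <- max(12, 0.15 * max(speed[idx]))
        a <- idx[1]
        while (a > 1 && speed[a - 1] > hyst && !blink[a - 1]) a <- a - 1
        b <- idx[length(idx)]
        while (b < n && speed[b + 1] > hyst && !blink[b + 1]) b <- b + 1
        sac[a:b] <- TRUE
      }
    }
  }

  kind <- rep("fixation", n)
  kind[sac] <- "saccade"
  kind[blink] <- "blink"

  r <- rle(kind)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  ev <- data.frame(kind = r$values,
                   onset_ms = t[starts],
                   offset_ms = c(t[starts[-1]], t[n] + dt_ms),
                   x = NA_real_, y = NA_real_, excluded = FALSE,
                   stringsAsFactors = FALSE)
  for (i in seq_len(nrow(ev))) {
    if (ev$kind[i] == "fixation") {
      idx <- starts[i]:ends[i]
      ev$x[i] <- mean(x[idx]); ev$y[i] <- mean(y[idx])
      if (ev$offset_ms[i] - ev$onset_ms[i] < min_fix_ms) ev$excluded[i] <- TRUE
    }
  }
  ev
}

#' Label fixations with trial, condition, ROI and analysis-window flags
#'
#' Each fixation is assigned to the trial interval containing its onset and
#' to the nearest ROI center within `radius_deg` (Euclidean distance; exact
#' ties broken by the fixed ordering original > updated > repeated);
#' fixations farther than `radius_deg` from every center get `roi = "none"`.
#' `in_analysis_window` is FALSE when the fixation starts within `edge_ms`
#' of trial onset, ends within `edge_ms` of trial end, is shorter than the
#' minimum duration, or falls outside every trial.
#'
#' @param fixations event table from [detect_eye_events()] (fixation rows
#'   are used).
#' @param trials data.frame: trial, onset_ms, offset_ms, condition, memory.
#' @param rois data.frame: roi, x, y (centers in degrees); defaults to the
#'   simulator's geometry for the three object-locations.
#' @param radius_deg ROI radius (degrees, default 6).
#' @param edge_ms guard interval after trial onset / before trial end (ms).
#' @return data.frame of labelled fixations: fixation columns + trial,
#'   condition, roi, memory, in_analysis_window.
#' @export
assign_fixations_to_rois <- function(fixations, trials,
                                     rois = NULL, radius_deg = 6,
                                     edge_ms = 500) {
  fx <- fixations[fixations$kind == "fixation", , drop = FALSE]
  if (is.null(rois)) {
    g <- roi_geometry()
    rois <- g[g$roi %in% c("original", "updated", "repeated"), ]
  }
  roi_order <- c("original", "updated", "repeated")
  rois <- rois[order(match(rois$roi, roi_order)), ]
  m <- nrow(fx)
  out_trial <- integer(m); out_cond <- character(m)
  out_roi <- character(m); out_mem <- character(m); in_win <- logical(m)
  for (i in seq_len(m)) {
    tr <- which(fx$onset_ms[i] >= trials$onset_ms &
                  fx$onset_ms[i] < trials$offset_ms)
    if (length(tr) == 0) {
      out_trial[i] <- NA_integer_
      out_cond[i] <- NA_character_; out_mem[i] <- NA_character_
      out_roi[i] <- "none"; in_win[i] <- FALSE
      next
    }
    tr <- tr[1]
    out_trial[i] <- trials$trial[tr]
    out_cond[i] <- trials$condition[tr]
    out_mem[i] <- trials$memory[tr]
    d <- sqrt((rois$x - fx$x[i])^2 + (rois$y - fx$y[i])^2)
    if (min(d) > radius_deg) {
      out_roi[i] <- "none"
    } else {
      out_roi[i] <- rois$roi[which.min(d)]  # ties: first in fixed order
    }
    in_win[i] <- fx$onset_ms[i] >= trials$onset_ms[tr] + edge_ms &&
      fx$offset_ms[i] <= trials$offset_ms[tr] - edge_ms &&
      !isTRUE(fx$excluded[i])
  }
  cbind(fx, data.frame(trial = out_trial, condition = out_cond,
                       roi = out_roi, memory = out_mem,
                       in_analysis_window = in_win,
                       stringsAsFactors = FALSE))
}

#' Viewing-proportion timecourse per trial and ROI
#'
#' Fraction of each time bin covered by fixations on each ROI, per trial.
#' Proportions are in \[0, 1\] and sum over ROIs to at most 1 per bin.
#'
#' @param labeled labelled fixations from [assign_fixations_to_rois()].
#' @param trials trial table.
#' @param bin_ms bin width (ms, > 0; default 2 = sample resolution).
#' @param rois ROI labels to track.
#' @return list of class `viewing_timecourse`: `prop` array
#'   (trials x rois x bins), `bin_ms`, `times_ms` (bin starts, relative to
#'   trial onset), `rois`, `trials`.
#' @export
viewing_timecourse <- function(labeled, trials, bin_ms = 2,
                               rois = c("original", "updated", "repeated")) {
  check(bin_ms > 0, "bin_ms must be positive")
  lens <- trials$offset_ms - trials$onset_ms
  n_bins <- ceiling(max(lens) / bin_ms)
  n_tr <- nrow(trials)
  prop <- array(0, c(n_tr, length(rois), n_bins))
  for (i in seq_len(nrow(labeled))) {
    ri <- match(labeled$roi[i], rois)
    if (is.na(ri) || is.na(labeled$trial[i])) next
    ti <- match(labeled$trial[i], trials$trial)
    rel0 <- labeled$onset_ms[i] - trials$onset_ms[ti]
    rel1 <- min(labeled$offset_ms[i] - trials$onset_ms[ti], lens[ti])
    if (rel1 <= 0 || rel0 >= lens[ti]) next
    rel0 <- max(rel0, 0)
    b0 <- floor(rel0 / bin_ms) + 1
    b1 <- min(ceiling(rel1 / bin_ms), n_bins)
    for (b in b0:b1) {
      lo <- (b - 1) * bin_ms; hi <- b * bin_ms
      cover <- max(0, min(rel1, hi) - max(rel0, lo))
      prop[ti, ri, b] <- prop[ti, ri, b] + cover / bin_ms
    }
  }
  prop <- pmin(prop, 1)
  structure(list(prop = prop, bin_ms = bin_ms,
                 times_ms = (seq_len(n_bins) - 1) * bin_ms, rois = rois,
                 trials = trials),
            class = "viewing_timecourse")
}

#' Behavioral subsequent-memory effect on a viewing timecourse
#'
#' Compares the probability of viewing one ROI between remembered and
#' forgotten trials at every time bin, with cluster correction over time
#' (1-D adjacency): per-bin statistic = mean difference, null built by
#' shuffling memory labels across trials.
#'
#' @param tc a `viewing_timecourse`.
#' @param roi ROI to analyse.
#' @param memory character vector of per-trial labels
#'   ("remembered"/"forgotten"); defaults to the trial table inside `tc`.
#' @param n_perm permutations (default 1000).
#' @param tail "one" (remembered > forgotten) or "two".
#' @param seed RNG seed.
#' @return a `cluster_result` plus `stat` and `times_ms`.
#' @export
behavioral_sme_timecourse <- function(tc, roi = "updated", memory = NULL,
                                      n_perm = 1000, tail = "two", seed = 1) {
  if (is.null(memory)) memory <- tc$trials$memory
  ri <- match(roi, tc$rois)
  check(!is.na(ri), "unknown ROI")
  M <- tc$prop[, ri, , drop = FALSE]
  M <- matrix(M, dim(tc$prop)[1], dim(tc$prop)[3])
  is_rem <- memory == "remembered"
  check(sum(is_rem) >= 2 && sum(!is_rem) >= 2,
        "need at least 2 trials per memory class")
  obs <- colMeans(M[is_rem, , drop = FALSE]) -
    colMeans(M[!is_rem, , drop = FALSE])
  set.seed(seed)
  n_tr <- nrow(M); n_rem <- sum(is_rem)
  null_stats <- matrix(0, n_perm, ncol(M))
  for (b in seq_len(n_perm)) {
    idx <- sample.int(n_tr, n_rem)
    null_stats[b, ] <- colMeans(M[idx, , drop = FALSE]) -
      colMeans(M[-idx, , drop = FALSE])
  }
  res <- cluster_from_null(obs, null_stats, tail = tail)
  res$stat <- obs
  res$times_ms <- tc$times_ms
  res
}
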