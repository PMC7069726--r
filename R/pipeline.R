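# Orchestration: simulate (or load) per-subject sessions, parse gaze, label
# fixations, epoch the LFP around fixation classes, and run the standard
# contrasts (retrieval, associative novelty, phase angles, PAC), each with
# event accounting and seeded, cluster-corrected group inference treating
# subject as the blocking unit.

#' Default pipeline configuration
#'
#' @param seed master seed; all stage seeds derive from it.
#' @param itc_freqs frequencies for ITC maps (Hz).
#' @param t_decim keep every `t_decim`-th time sample in ITC maps.
#' @param window,buffer_ms fixation epoch window and buffer (ms).
#' @param pac_window,pac_buffer_ms PAC epoch window and buffer (ms).
#' @param phase_freqs,amp_freqs PAC comodulogram grids (Hz).
#' @param n_perm cluster permutations; `n_draws` ITC subsample draws;
#'   `n_surr` PAC surrogates; `ww_n_perm` Watson-Williams permutations.
#' @param pre_angle_window,post_angle_window phase-angle windows (ms).
#' @param theta_freq frequency at which phase angles are read (Hz).
#' @param alpha cluster significance level; `alpha_phase` phase-difference
#'   significance level.
#' @param bonferroni correct the session-level flags for the number of
#'   contrasts in the report (default TRUE).
#' @return named list of configuration values.
#' @export
pipeline_config <- function(seed = 1,
                            itc_freqs = log_freqs(12, 2, 8),
                            t_decim = 5,
                            window = c(-750, 750), buffer_ms = 1250,
                            pac_window = c(-50, 750), pac_buffer_ms = 400,
                            phase_freqs = log_freqs(4, 3, 7),
                            amp_freqs = log_freqs(6, 80, 120),
                            n_perm = 500, n_draws = 20, n_surr = 80,
                            ww_n_perm = 500,
                            pre_angle_window = c(-420, -380),
                            post_angle_window = c(80, 120),
                            theta_freq = 5,
                            alpha = 0.05, alpha_phase = 0.01,
                            bonferroni = TRUE) {
  as.list(environment())
}

#' Simulate a complete multi-subject session
#'
#' Each subject gets an independent LFP + fixation stream + gaze record;
#' the gaze is parsed back into events with [detect_eye_events()] and
#' fixations are labelled from the trial table, so the full analysis path is
#' exercised. With `effect = TRUE` the generator builds in the three target
#' effects: peak phase-locking 400 ms before fixations to the original
#' object-location on Mismatch trials, trough phase-locking 100 ms after
#' fixations to the updated object-location, and theta-gamma coupling on
#' Mismatch trials. With `effect = FALSE` all locking and coupling is off.
#'
#' @param seed session seed.
#' @param n_subjects number of subjects (default 5).
#' @param duration_s recording duration per subject (seconds).
#' @param effect build in the ground-truth effects (default TRUE).
#' @param kappa locking concentration for the effect classes.
#' @param coupling_depth PAC depth for Mismatch trials under `effect`.
#' @return list of per-subject datasets: `recording`, `events` (labelled
#'   fixations), `trials`, `truth`, `config`.
#' @export
simulate_session <- function(seed, n_subjects = 5, duration_s = 60,
                             effect = TRUE, kappa = 4,
                             coupling_depth = 0.8) {
  lapply(seq_len(n_subjects), function(s) {
    cfg <- sim_config(
      duration_s = duration_s, fs = 500,
      aperiodic_exponent = 1.5, theta_freq = 5, theta_amp = 1,
      gamma_freq = 90, gamma_amp = 0.4,
      coupling_phase = pi,
      coupling_depth = 0,
      coupling_depth_by_condition =
        if (effect) c(Mismatch = coupling_depth, Match = 0) else NULL,
      n_trials = max(8, round(duration_s / 4)),
      fixation_rate = 3,
      kappa_by_condition = if (effect) {
        c("Mismatch/original" = kappa, "Mismatch/updated" = kappa)
      } else c(Match = 0, Mismatch = 0),
      preferred_phase_by_condition =
        c("Mismatch/original" = 0, "Mismatch/updated" = pi),
      lock_offset_ms_by_condition =
        c("Mismatch/original" = -400, "Mismatch/updated" = 100),
      p_remember = 0.72,
      seed = derive_seed(seed, 100L + s))
    sim <- simulate_lfp(cfg)
    ev_true <- simulate_fixation_stream(cfg, sim$truth)
    gaze <- simulate_gaze(cfg, ev_true)
    parsed <- detect_eye_events(gaze)
    labeled <- assign_fixations_to_rois(parsed, sim$truth$trials)
    list(recording = sim$recording, events = labeled,
         trials = sim$truth$trials, truth = sim$truth, config = cfg)
  })
}

# Select fixation onsets for a contrast class. `class` is a list with any of
# condition, roi, memory; NULL fields match everything.
class_onsets <- function(events, class, use_analysis_window = TRUE,
                         clean_ms = 0, clean_side = c("pre", "post")) {
  clean_side <- match.arg(clean_side)
  fx <- events[events$kind == "fixation", , drop = FALSE]
  sel <- rep(TRUE, nrow(fx))
  if (!is.null(class$condition)) sel <- sel & fx$condition %in% class$condition
  if (!is.null(class$roi)) sel <- sel & fx$roi %in% class$roi
  if (!is.null(class$memory)) sel <- sel & fx$memory %in% class$memory
  sel[is.na(sel)] <- FALSE
  if (use_analysis_window) sel <- sel & fx$in_analysis_window
  n_in <- sum(sel, na.rm = TRUE)
  if (clean_ms > 0) {
    all_on <- fx$onset_ms
    ok <- vapply(which(sel), function(i) {
      if (clean_side == "pre") {
        !any(all_on > fx$onset_ms[i] - clean_ms & all_on < fx$onset_ms[i])
      } else {
        !any(all_on > fx$onset_ms[i] &
               all_on < fx$onset_ms[i] + clean_ms)
      }
    }, logical(1))
    sel[which(sel)][!ok] <- FALSE
  }
  list(onsets = fx$onset_ms[sel], n_in = n_in,
       n_clean = sum(sel))
}

describe_class <- function(class) {
  paste(vapply(names(class), function(k) {
    paste0(k, "=", paste(class[[k]], collapse = "|"))
  }, character(1)), collapse = ", ")
}

# Class onsets with an explicit error naming the filter when empty.
class_onsets_checked <- function(events, class, min_n = 2, ...) {
  on <- class_onsets(events, class, ...)
  if (length(on$onsets) < min_n) {
    stop("fixation class empty after filtering [", describe_class(class),
         "]: ", length(on$onsets), " event(s)", call. = FALSE)
  }
  on
}

# Per-subject ITC maps for two classes at matched N. `map_window` restricts
# the time axis of the statistical map (e.g. pre-fixation only for the
# retrieval contrast, post-fixation only for novelty).
subject_itc_pair <- function(dataset, class_a, class_b, config, seed,
                             map_window = NULL) {
  on_a <- class_onsets_checked(dataset$events, class_a)
  on_b <- class_onsets_checked(dataset$events, class_b)
  ep_a <- extract_epochs(dataset$recording, on_a$onsets,
                         window = config$window,
                         buffer_ms = config$buffer_ms)
  ep_b <- extract_epochs(dataset$recording, on_b$onsets,
                         window = config$window,
                         buffer_ms = config$buffer_ms)
  tf_a <- morlet_transform(ep_a, config$itc_freqs)
  tf_b <- morlet_transform(ep_b, config$itc_freqs)
  tsel <- seq(1, dim(tf_a$phase)[3], by = config$t_decim)
  if (!is.null(map_window)) {
    tsel <- tsel[window_mask(tf_a$times_ms[tsel], map_window)]
  }
  pha <- tf_a$phase[, , tsel, drop = FALSE]
  phb <- tf_b$phase[, , tsel, drop = FALSE]
  ic <- itc_contrast_subsampled(pha, phb, n_draws = config$n_draws,
                                seed = seed)
  list(itc_a = ic$itc_a, itc_b = ic$itc_b, n_matched = ic$n_matched,
       times_ms = tf_a$times_ms[tsel],
       counts = data.frame(class = c("A", "B"),
                           events_in = c(on_a$n_in, on_b$n_in),
                           epochs = c(nrow(ep_a$data), nrow(ep_b$data))),
       tf_a = tf_a, tf_b = tf_b, tsel = tsel)
}

#' Run a single contrast over a multi-subject session
#'
#' @param datasets list of per-subject datasets (see [simulate_session()]).
#' @param spec contrast specification: list with `name`, `class_a`,
#'   `class_b` (lists with condition/roi/memory), `measure` (one of
#'   "itc", "phase_angle", "pac"), optional `tail` ("one"/"two").
#' @param config a [pipeline_config()].
#' @return report fragment: `name`, `measure`, per-measure results,
#'   `counts`, `significant` (logical flag at the configured alpha), `seed`.
#' @export
run_contrast <- function(datasets, spec, config = pipeline_config()) {
  tail <- if (is.null(spec$tail)) "one" else spec$tail
  seed <- derive_seed(config$seed, 17L + nchar(spec$name))
  n_sub <- length(datasets)
  if (spec$measure == "itc") {
    pairs <- lapply(seq_len(n_sub), function(s) {
      subject_itc_pair(datasets[[s]], spec$class_a, spec$class_b, config,
                       seed = derive_seed(seed, s),
                       map_window = spec$map_window)
    })
    dims <- dim(pairs[[1]]$itc_a)
    xa <- array(0, c(n_sub, dims[1], dims[2]))
    xb <- array(0, c(n_sub, dims[1], dims[2]))
    for (s in seq_len(n_sub)) {
      xa[s, , ] <- pairs[[s]]$itc_a
      xb[s, , ] <- pairs[[s]]$itc_b
    }
    cl <- cluster_permutation_test(xa, xb, tail = tail,
                                   n_perm = config$n_perm, seed = seed)
    sig <- any(cl$p_fwe < config$alpha)
    g <- if (sig) {
      mask <- cl$masks[[which.min(cl$p_fwe)]]
      per_sub_a <- vapply(seq_len(n_sub), function(s) mean(xa[s, , ][mask]),
                          numeric(1))
      per_sub_b <- vapply(seq_len(n_sub), function(s) mean(xb[s, , ][mask]),
                          numeric(1))
      hedges_g_dependent(per_sub_a, per_sub_b)$g
    } else NA_real_
    counts <- do.call(rbind, lapply(seq_len(n_sub), function(s) {
      cbind(subject = s, pairs[[s]]$counts)
    }))
    return(list(name = spec$name, measure = "itc", clusters = cl,
                freqs = config$itc_freqs, times_ms = pairs[[1]]$times_ms,
                hedges_g = g, counts = counts, significant = sig,
                seed = seed, n_perm = config$n_perm))
  }
  if (spec$measure == "phase_angle") {
    fi <- which.min(abs(config$itc_freqs - config$theta_freq))
    collect <- function(class, win) {
      angs <- c()
      for (s in seq_len(n_sub)) {
        on <- class_onsets_checked(datasets[[s]]$events, class)
        ep <- extract_epochs(datasets[[s]]$recording, on$onsets,
                             window = config$window,
                             buffer_ms = config$buffer_ms)
        tf <- morlet_transform(ep, config$itc_freqs)
        tmask <- window_mask(tf$times_ms, win)
        ph <- tf$phase[, fi, tmask, drop = FALSE]
        angs <- c(angs, apply(ph, 1, function(v) circ_mean(v)$mean))
      }
      angs
    }
    a <- collect(spec$class_a, config$pre_angle_window)
    b <- collect(spec$class_b, config$post_angle_window)
    ww <- watson_williams_perm(a, b, n_perm = config$ww_n_perm, seed = seed)
    return(list(name = spec$name, measure = "phase_angle",
                summary_a = circular_mean_ci(a), summary_b = circular_mean_ci(b),
                watson_williams = ww,
                significant = ww$p < config$alpha_phase,
                counts = data.frame(class = c("A", "B"),
                                    events = c(length(a), length(b))),
                seed = seed, n_perm = config$ww_n_perm))
  }
  if (spec$measure == "pac") {
    maps_a <- list(); maps_b <- list()
    for (s in seq_len(n_sub)) {
      get_map <- function(class, k) {
        on <- class_onsets_checked(datasets[[s]]$events, class)
        ep <- extract_epochs(datasets[[s]]$recording, on$onsets,
                             window = config$pac_window,
                             buffer_ms = config$pac_buffer_ms)
        comodulogram_z(ep, phase_freqs = config$phase_freqs,
                       amp_freqs = config$amp_freqs, n_surr = config$n_surr,
                       seed = derive_seed(seed, s * 10L + k))$mi_z
      }
      maps_a[[s]] <- get_map(spec$class_a, 1L)
      maps_b[[s]] <- get_map(spec$class_b, 2L)
    }
    dims <- dim(maps_a[[1]])
    xa <- array(0, c(n_sub, dims[1], dims[2]))
    xb <- array(0, c(n_sub, dims[1], dims[2]))
    for (s in seq_len(n_sub)) {
      xa[s, , ] <- maps_a[[s]]; xb[s, , ] <- maps_b[[s]]
    }
    xa[!is.finite(xa)] <- 0; xb[!is.finite(xb)] <- 0
    cl <- cluster_permutation_test(xa, xb, tail = tail,
                                   n_perm = config$n_perm, seed = seed)
    sig <- any(cl$p_fwe < config$alpha)
    return(list(name = spec$name, measure = "pac", clusters = cl,
                phase_freqs = config$phase_freqs,
                amp_freqs = config$amp_freqs,
                mi_z_a = maps_a, mi_z_b = maps_b, significant = sig,
                seed = seed, n_perm = config$n_perm))
  }
  if (spec$measure == "erp_reset") {
    # pooled fixation-locked epochs for class A across subjects
    eps <- lapply(seq_len(n_sub), function(s) {
      on <- class_onsets_checked(datasets[[s]]$events, spec$class_a)
      extract_epochs(datasets[[s]]$recording, on$onsets,
                     window = config$window, buffer_ms = config$buffer_ms)
    })
    data <- do.call(rbind, lapply(eps, function(e) e$data))
    er <- erp_power_reset(data, freqs = config$itc_freqs,
                          n_perm = config$n_perm, seed = seed,
                          times_ms = eps[[1]]$times_ms, fs = eps[[1]]$fs)
    sig <- length(er$clusters$p_fwe) > 0 && any(er$clusters$p_fwe < config$alpha)
    return(list(name = spec$name, measure = "erp_reset",
                clusters = er$clusters, freqs = er$freqs, stat = er$stat,
                significant = sig, seed = seed, n_perm = config$n_perm))
  }
  if (spec$measure == "viewing") {
    # pooled trials across subjects; remembered-vs-forgotten SME timecourse
    tcs <- lapply(seq_len(n_sub), function(s) {
      viewing_timecourse(datasets[[s]]$events, datasets[[s]]$trials,
                         bin_ms = if (is.null(spec$bin_ms)) 50 else
                           spec$bin_ms)
    })
    n_bins <- min(vapply(tcs, function(tc) dim(tc$prop)[3], numeric(1)))
    prop <- do.call(abind_first, lapply(tcs, function(tc) {
      tc$prop[, , seq_len(n_bins), drop = FALSE]
    }))
    pooled <- structure(list(prop = prop, bin_ms = tcs[[1]]$bin_ms,
                             times_ms = tcs[[1]]$times_ms[seq_len(n_bins)],
                             rois = tcs[[1]]$rois,
                             trials = do.call(rbind, lapply(datasets,
                                                            `[[`, "trials"))),
                        class = "viewing_timecourse")
    sme <- behavioral_sme_timecourse(pooled,
                                     roi = if (is.null(spec$roi)) "updated"
                                     else spec$roi,
                                     n_perm = config$n_perm, seed = seed)
    sig <- length(sme$p_fwe) > 0 && any(sme$p_fwe < config$alpha)
    return(list(name = spec$name, measure = "viewing", clusters = sme,
                times_ms = sme$times_ms, significant = sig, seed = seed,
                n_perm = config$n_perm))
  }
  stop("unknown measure: ", spec$measure)
}

# rbind along the first (trial) dimension of trials x roi x bin arrays
abind_first <- function(...) {
  mats <- list(...)
  d <- dim(mats[[1]])
  out <- array(0, c(sum(vapply(mats, function(m) dim(m)[1], numeric(1))),
                    d[2], d[3]))
  at <- 0
  for (m in mats) {
    out[at + seq_len(dim(m)[1]), , ] <- m
    at <- at + dim(m)[1]
  }
  out
}

#' Standard contrast specifications
#'
#' retrieval: fixations to the original vs updated object-location on
#' Mismatch trials (pre-fixation phase-locking). novelty: fixations to the
#' updated location on Mismatch trials vs the repeated location on Match
#' trials, restricted to remembered trials (post-fixation phase-locking).
#' phase_angle: pre-window phases of retrieval fixations vs post-window
#' phases of novelty fixations. pac: theta-gamma coupling, updated/Mismatch
#' vs repeated/Match.
#'
#' @return named list of contrast specs for [run_contrast()].
#' @export
standard_contrasts <- function() {
  list(
    retrieval = list(name = "retrieval", measure = "itc",
                     class_a = list(condition = "Mismatch", roi = "original"),
                     class_b = list(condition = "Mismatch", roi = "updated"),
                     tail = "one", map_window = c(-750, 50)),
    novelty = list(name = "novelty", measure = "itc",
                   class_a = list(condition = "Mismatch", roi = "updated",
                                  memory = "remembered"),
                   class_b = list(condition = "Match", roi = "repeated",
                                  memory = "remembered"),
                   tail = "one", map_window = c(-50, 750)),
    phase_angle = list(name = "phase_angle", measure = "phase_angle",
                       class_a = list(condition = "Mismatch",
                                      roi = "original"),
                       class_b = list(condition = "Mismatch",
                                      roi = "updated")),
    pac = list(name = "pac", measure = "pac",
               class_a = list(condition = "Mismatch", roi = "updated"),
               class_b = list(condition = "Match", roi = "repeated"),
               tail = "one"))
}

#' Run the full standard analysis over a session
#'
#' Per-contrast fragments report uncorrected significance; the session-level
#' `flags` apply a Bonferroni correction across the contrasts run (the
#' report's family of tests), unless `config$bonferroni` is FALSE. With a
#' Bonferroni-corrected cluster threshold the sign-flip null needs
#' resolution finer than the threshold (p-value floor 2^-n_subjects), so
#' session-level flagging needs at least 7 subjects at the default alpha.
#'
#' @param datasets list of per-subject datasets.
#' @param config a [pipeline_config()].
#' @return analysis report: per-contrast fragments, `flags` (named logical:
#'   which contrasts are flagged after correction), `seed`, `n_subjects`.
#' @export
run_session <- function(datasets, config = pipeline_config()) {
  specs <- standard_contrasts()
  frags <- lapply(specs, function(sp) run_contrast(datasets, sp, config))
  corr <- if (isTRUE(config$bonferroni)) length(frags) else 1
  flags <- vapply(frags, function(fr) {
    if (!is.null(fr$clusters)) {
      length(fr$clusters$p_fwe) > 0 &&
        any(fr$clusters$p_fwe < config$alpha / corr)
    } else if (!is.null(fr$watson_williams)) {
      fr$watson_williams$p < config$alpha_phase / corr
    } else isTRUE(fr$significant)
  }, logical(1))
  list(contrasts = frags, flags = flags, seed = config$seed,
       n_subjects = length(datasets))
}

#' Between-band PAC comparisons
#'
#' Collapses per-subject comodulograms to one profile per phase band
#' (max MI_Z over the band's phase frequencies, per amplitude frequency) and
#' cluster-tests every band pair across subjects (1-D over amplitude
#' frequency, two-tailed).
#'
#' @param comods_by_subject list (one per subject) of `comodulogram`
#'   objects on a shared wide phase grid.
#' @param bands named list of phase bands (Hz).
#' @param n_perm cluster permutations.
#' @param seed RNG seed.
#' @return list: `profiles` (subject x band x amp-freq array), `pairs`
#'   (list of cluster results per band pair), `bands`.
#' @export
run_band_comparisons <- function(comods_by_subject,
                                 bands = list(low_theta = c(1, 3),
                                              theta = c(4, 6),
                                              fast_theta = c(7, 10)),
                                 n_perm = 500, seed = 1) {
  pf <- comods_by_subject[[1]]$phase_freqs
  af <- comods_by_subject[[1]]$amp_freqs
  for (cm in comods_by_subject) {
    check(isTRUE(all.equal(cm$phase_freqs, pf)) &&
            isTRUE(all.equal(cm$amp_freqs, af)), "mismatched grids")
  }
  n_sub <- length(comods_by_subject)
  prof <- array(0, c(n_sub, length(bands), length(af)),
                dimnames = list(NULL, names(bands), NULL))
  for (s in seq_len(n_sub)) {
    mz <- comods_by_subject[[s]]$mi_z
    for (b in seq_along(bands)) {
      sel <- pf >= bands[[b]][1] & pf <= bands[[b]][2]
      check(any(sel), "band outside grid")
      prof[s, b, ] <- apply(mz[sel, , drop = FALSE], 2, max, na.rm = TRUE)
    }
  }
  pair_names <- utils::combn(names(bands), 2, paste, collapse = "_vs_")
  pair_idx <- utils::combn(length(bands), 2)
  pairs <- lapply(seq_along(pair_names), function(k) {
    x <- prof[, pair_idx[1, k], , drop = FALSE]
    y <- prof[, pair_idx[2, k], , drop = FALSE]
    cluster_permutation_test(matrix(x, n_sub), matrix(y, n_sub),
                             tail = "two", n_perm = n_perm,
                             seed = derive_seed(seed, k))
  })
  names(pairs) <- pair_names
  list(profiles = prof, pairs = pairs, bands = bands)
}

#' Serialize an analysis report to JSON
#'
#' Cluster masks are emitted as bin indices; every p-value is accompanied by
#' its permutation count and seed.
#'
#' @param report output of [run_session()].
#' @param path output file.
#' @return invisibly, the path.
#' @export
report_to_json <- function(report, path) {
  strip <- function(fr) {
    out <- list(name = fr$name, measure = fr$measure,
                significant = fr$significant, seed = fr$seed,
                n_perm = fr$n_perm)
    if (!is.null(fr$clusters)) {
      out$clusters <- lapply(seq_along(fr$clusters$mass), function(k) {
        list(mass = fr$clusters$mass[k], p_fwe = fr$clusters$p_fwe[k],
             bins = which(as.vector(fr$clusters$masks[[k]])))
      })
    }
    if (!is.null(fr$watson_williams)) {
      out$watson_williams <- fr$watson_williams[c("F", "Z_F", "p", "n_perm")]
    }
    if (!is.null(fr$hedges_g)) out$hedges_g <- fr$hedges_g
    if (!is.null(fr$counts)) out$counts <- fr$counts
    out
  }
  obj <- list(schema = "thetagaze-report-1",
              seed = report$seed, n_subjects = report$n_subjects,
              flags = as.list(report$flags),
              contrasts = lapply(report$contrasts, strip))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = 10,
                       pretty = TRUE, force = TRUE)
  invisible(path)
}
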