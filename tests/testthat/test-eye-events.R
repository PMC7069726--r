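# Gaze parsing, ROI labelling, viewing timecourses.

test_that("parser recovers programmed saccades with <= 4 ms onset error", {
  cfg <- sim_config(duration_s = 60, fixation_rate = 3, blink_rate = 0.1,
                    seed = 31)
  sim <- simulate_lfp(cfg)
  ev <- simulate_fixation_stream(cfg, sim$truth)
  gaze <- simulate_gaze(cfg, ev)
  gt <- attr(gaze, "gaze_truth")
  parsed <- detect_eye_events(gaze)
  sac_t <- gt[gt$kind == "saccade" & gt$amplitude >= 1, ]
  det <- parsed[parsed$kind == "saccade", ]
  err <- vapply(sac_t$onset_ms, function(o) min(abs(det$onset_ms - o)),
                numeric(1))
  expect_gte(mean(err <= 4), 0.95)
  # blinks recovered, no saccades at dropout edges
  bl_t <- gt[gt$kind == "blink", ]
  if (nrow(bl_t) > 0) {
    bl_d <- parsed[parsed$kind == "blink", ]
    expect_gte(nrow(bl_d), nrow(bl_t))
    for (i in seq_len(nrow(bl_t))) {
      near <- abs(det$onset_ms - bl_t$onset_ms[i]) < 50 |
        abs(det$onset_ms - bl_t$offset_ms[i]) < 50
      expect_false(any(near))
    }
  }
})

test_that("sub-threshold jitter yields zero spurious saccades", {
  set.seed(32)
  g <- data.frame(time_ms = seq(0, 10000, 2),
                  x_deg = rnorm(5001, 0, 0.02),
                  y_deg = rnorm(5001, 0, 0.02), pupil = 1000)
  parsed <- detect_eye_events(g)
  expect_equal(sum(parsed$kind == "saccade"), 0)
})

test_that("parser output partitions every sample and flags short fixations", {
  cfg <- sim_config(duration_s = 30, fixation_rate = 3, blink_rate = 0.2,
                    seed = 33)
  sim <- simulate_lfp(cfg)
  ev <- simulate_fixation_stream(cfg, sim$truth)
  gaze <- simulate_gaze(cfg, ev)
  parsed <- detect_eye_events(gaze)
  # partition: contiguous, non-overlapping, covers the record
  expect_equal(parsed$onset_ms[1], gaze$time_ms[1])
  expect_equal(parsed$onset_ms[-1], parsed$offset_ms[-nrow(parsed)])
  expect_true(all(parsed$offset_ms > parsed$onset_ms))
  short <- parsed$kind == "fixation" &
    (parsed$offset_ms - parsed$onset_ms) < 80
  expect_true(all(parsed$excluded[short]))
  expect_false(any(parsed$excluded[parsed$kind == "fixation" & !short]))
})

test_that("all-dropout input produces a single blink", {
  g <- data.frame(time_ms = seq(0, 1000, 2), x_deg = 0, y_deg = 0, pupil = 0)
  parsed <- detect_eye_events(g)
  expect_equal(nrow(parsed), 1)
  expect_equal(parsed$kind, "blink")
  expect_error(detect_eye_events(g[c(2, 1, 3), ]), "increasing")
})

test_that("ROI labelling uses the 6-degree radius and nearest-center rule", {
  trials <- data.frame(trial = 1, onset_ms = 0, offset_ms = 10000,
                       condition = "Mismatch", memory = "remembered")
  fx <- data.frame(kind = "fixation",
                   onset_ms = c(1000, 2000, 3000, 4000),
                   offset_ms = c(1500, 2500, 3500, 4500),
                   x = c(-9, -9 + 6.1 * sqrt(0.5), 0, -1),
                   y = c(0, 6.1 * sqrt(0.5), 9, 0.5),
                   excluded = FALSE)
  lab <- assign_fixations_to_rois(fx, trials)
  expect_equal(lab$roi, c("original", "none", "repeated", "none"))
  # fixation within 6 deg of two centers: nearest wins
  fx2 <- data.frame(kind = "fixation", onset_ms = 1000, offset_ms = 1500,
                    x = 0, y = 5, excluded = FALSE)
  rois <- data.frame(roi = c("original", "updated"),
                     x = c(0, 0), y = c(0, 9.5))
  lab2 <- assign_fixations_to_rois(fx2, trials, rois = rois)
  expect_equal(lab2$roi, "updated")   # 4.5 deg vs 5 deg
  # analysis-window guard
  fx3 <- data.frame(kind = "fixation", onset_ms = c(100, 5000),
                    offset_ms = c(700, 5600), x = -9, y = 0,
                    excluded = FALSE)
  lab3 <- assign_fixations_to_rois(fx3, trials)
  expect_equal(lab3$in_analysis_window, c(FALSE, TRUE))
  # fixation outside all trials
  fx4 <- data.frame(kind = "fixation", onset_ms = 20000, offset_ms = 20500,
                    x = -9, y = 0, excluded = FALSE)
  lab4 <- assign_fixations_to_rois(fx4, trials)
  expect_true(is.na(lab4$trial))
  expect_false(lab4$in_analysis_window)
})

test_that("viewing timecourse computes interval coverage", {
  trials <- data.frame(trial = 1, onset_ms = 0, offset_ms = 1000,
                       condition = "Mismatch", memory = "remembered")
  lab <- data.frame(kind = "fixation", onset_ms = c(0, 500),
                    offset_ms = c(500, 1000), x = 0, y = 0,
                    excluded = FALSE, trial = 1, condition = "Mismatch",
                    roi = c("original", "updated"), memory = "remembered",
                    in_analysis_window = TRUE)
  tc <- viewing_timecourse(lab, trials, bin_ms = 100)
  expect_equal(dim(tc$prop), c(1, 3, 10))
  expect_equal(tc$prop[1, 1, ], c(rep(1, 5), rep(0, 5)))
  expect_equal(tc$prop[1, 2, ], c(rep(0, 5), rep(1, 5)))
  expect_true(all(apply(tc$prop, c(1, 3), sum) <= 1 + 1e-12))
  # whole-trial single fixation
  lab1 <- lab[1, ]; lab1$offset_ms <- 1000
  tc1 <- viewing_timecourse(lab1, trials, bin_ms = 100)
  expect_equal(tc1$prop[1, 1, ], rep(1, 10))
  # no fixations
  tc0 <- viewing_timecourse(lab[0, ], trials, bin_ms = 100)
  expect_true(all(tc0$prop == 0))
  expect_error(viewing_timecourse(lab, trials, bin_ms = 0), "positive")
})

test_that("behavioral SME cluster test detects injected effects only", {
  mk_tc <- function(effect, seed) {
    set.seed(seed)
    n_tr <- 60; n_bins <- 40
    prop <- array(runif(n_tr * 2 * n_bins, 0.1, 0.5), c(n_tr, 2, n_bins))
    memory <- rep(c("remembered", "forgotten"), each = n_tr / 2)
    if (effect) {
      prop[memory == "remembered", 1, 10:20] <-
        prop[memory == "remembered", 1, 10:20] + 0.3
    }
    structure(list(prop = prop, bin_ms = 50,
                   times_ms = (0:(n_bins - 1)) * 50,
                   rois = c("updated", "original"),
                   trials = data.frame(trial = 1:n_tr, memory = memory)),
              class = "viewing_timecourse")
  }
  r1 <- behavioral_sme_timecourse(mk_tc(TRUE, 2), roi = "updated",
                                  n_perm = 400, seed = 3)
  sig <- which(r1$p_fwe < 0.05)
  expect_gte(length(sig), 1)
  covered <- Reduce(`|`, r1$masks[sig])
  expect_gte(sum(covered[10:20]), 6)
  # identical classes: no clusters
  tc_null <- mk_tc(FALSE, 4)
  tc_null$prop[31:60, , ] <- tc_null$prop[1:30, , ]
  r0 <- behavioral_sme_timecourse(tc_null, roi = "updated", n_perm = 300,
                                  seed = 5)
  expect_false(any(r0$p_fwe < 0.05))
  # single class errors
  tc1 <- mk_tc(FALSE, 6)
  expect_error(behavioral_sme_timecourse(tc1, roi = "updated",
                                         memory = rep("remembered", 60)),
               "memory class")
})
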