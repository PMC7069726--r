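# Modulation index, comodulograms, waveform features, confound regression.

test_that("modulation index matches analytic values", {
  # uniform amplitude across bins -> MI = 0
  set.seed(51)
  m0 <- modulation_index(runif(4000, -pi, pi), rep(1, 4000))
  expect_equal(m0$mi, 0)
  # all amplitude in one bin -> MI = 1
  expect_equal(modulation_index(rep(0.1, 100), rep(2, 100))$mi, 1)
  # half the bins at 0.1, half at 0 -> MI = ln2/ln20
  centers <- ((0:9) + 0.5) / 20 * 2 * pi - pi
  m2 <- modulation_index(rep(centers, 50), rep(1, 500))
  expect_equal(m2$mi, log(2) / log(20), tolerance = 1e-12)
  # direct KL-sum evaluation for an arbitrary hand-specified distribution
  # (amplitude per bin proportional to the target P)
  p_spec <- c(0.30, 0.20, 0.15, 0.10, 0.05, 0.05, 0.05, 0.04, 0.03, 0.03)
  centers10 <- ((0:9) + 0.5) / 10 * 2 * pi - pi
  ph <- rep(centers10, each = 50)
  amp <- rep(p_spec, each = 50)
  mi_direct <- sum(p_spec * log(p_spec * 10)) / log(10)
  m3 <- modulation_index(ph, amp, n_bins = 10)
  expect_equal(m3$mi, mi_direct, tolerance = 1e-12)
  expect_error(modulation_index(c(0, 1), c(0, 0)), "all zero")
  expect_error(modulation_index(c(0, 1), c(1, -1)), "non-negative")
})

test_that("MI is scale invariant and rotation invariant with bin rotation", {
  set.seed(52)
  ph <- runif(3000, -pi, pi)
  amp <- abs(1 + 0.5 * cos(ph)) + runif(3000, 0, 0.1)
  expect_equal(modulation_index(ph, amp)$mi,
               modulation_index(ph, 10 * amp)$mi, tolerance = 1e-12)
  # rotating phases by a whole bin leaves MI unchanged
  width <- 2 * pi / 20
  expect_equal(modulation_index(thetagaze:::wrap_pi(ph + width), amp)$mi,
               modulation_index(ph, amp)$mi, tolerance = 1e-12)
})

test_that("MI increases monotonically with coupling depth", {
  mis <- vapply(c(0, 0.3, 0.6, 0.9), function(d) {
    ep <- make_lfp_epochs(40, window = c(0, 1400), buffer_ms = 1250,
                          coupling_depth = d, seed = 13, spacing_s = 1.6)
    cm <- comodulogram_z(ep, phase_freqs = 5, amp_freqs = 90, n_surr = 5,
                         seed = 14)
    cm$mi_obs[1, 1]
  }, numeric(1))
  expect_true(all(diff(mis) > 0))
})

test_that("comodulogram recovers the programmed coupling pair", {
  ep <- make_lfp_epochs(120, window = c(0, 1500), buffer_ms = 1250,
                        coupling_depth = 0.8, coupling_phase = pi,
                        seed = 11, spacing_s = 4.05)
  cm <- comodulogram_z(ep, phase_freqs = log_freqs(10, 1, 10),
                       amp_freqs = log_freqs(13, 80, 200), n_surr = 200,
                       seed = 12)
  iz <- which(cm$mi_z == max(cm$mi_z, na.rm = TRUE), arr.ind = TRUE)
  expect_lte(abs(cm$phase_freqs[iz[1]] - 5), 1)
  expect_lte(abs(cm$amp_freqs[iz[2]] - 90), 10)
  expect_gt(max(cm$mi_z, na.rm = TRUE), 3)
})

test_that("theta frequency selection pools magnitude across conditions", {
  mk <- function(vals) {
    structure(list(mi_z = matrix(vals, 3, 2),
                   phase_freqs = c(4, 5, 6), amp_freqs = c(90, 120),
                   n_surr = 10, n_epochs = 10), class = "comodulogram")
  }
  a <- mk(c(1, 1, 1, 1, 4, 1))     # max |MI_Z| at 5 Hz
  b <- mk(c(3, 1, 1, 1, 1, 1))     # max at 4 Hz, smaller
  expect_equal(select_theta_frequency(list(a)), 5)
  expect_equal(select_theta_frequency(list(a, b)), 5)
  b2 <- mk(c(-6, 1, 1, 1, 1, 1))   # negative but larger magnitude at 4
  expect_equal(select_theta_frequency(list(a, b2)), 4)
  # tie -> lowest frequency
  tie <- mk(c(2, 2, 1, 2, 2, 1))
  expect_equal(select_theta_frequency(list(tie)), 4)
  expect_error(select_theta_frequency(list(a), band = c(20, 30)), "band")
})

test_that("waveform features behave analytically on sinusoids", {
  fs <- 500
  t <- seq(1 / fs, 4, by = 1 / fs)
  x <- matrix(sin(2 * pi * 5 * t), 1)
  wf <- waveform_features(x, fs)
  expect_equal(wf$s_peak, wf$s_trough, tolerance = 0.02)
  expect_equal(wf$asym, 0, tolerance = 0.1)
  wf2 <- waveform_features(2 * x, fs)
  expect_equal(wf2$s_peak, 2 * wf$s_peak, tolerance = 1e-6)
  expect_equal(wf2$amp, 2 * wf$amp, tolerance = 1e-6)
  # fast-rise sawtooth-like wave: rise shorter than decay -> negative asym
  saw <- 2 * ((5 * t) %% 1)
  saw <- ifelse(saw < 0.4, saw / 0.4, (2 - saw) / 1.6) - 0.5
  wfs <- waveform_features(matrix(saw, 1), fs, band = c(1, 10))
  expect_lt(wfs$asym, -0.05)
})

test_that("waveform regression isolates and removes feature dependence", {
  ep <- make_lfp_epochs(500, window = c(-50, 750), buffer_ms = 500,
                        seed = 41, spacing_s = 0.26)
  wf <- waveform_features(ep$data, fs = 500,
                          event_idx = which.min(abs(ep$times_ms - 0)))
  wf <- add_phase_deviation(wf, rep(c("A", "B"), length.out = nrow(wf)))
  set.seed(42)
  mi_fake <- 0.8 * scale(wf$power)[, 1] + rnorm(nrow(wf), 0, 0.3)
  adj <- adjust_pac_for_waveform(mi_fake, wf)
  rep_power <- adj$report[adj$report$set == "Power", ]
  expect_lt(rep_power$p, 1e-10)
  expect_lt(abs(cor(adj$adjusted, wf$power)), 0.05)
  # residuals orthogonal to every retained regressor
  for (f in setdiff(c("power", "sin_theta", "cos_theta", "s_peak",
                      "s_trough", "asym"), adj$dropped)) {
    expect_lt(abs(cor(adj$adjusted, wf[[f]])), 1e-10)
  }
  # independent MI_Z: adjusted ~ raw
  mi_null <- rnorm(nrow(wf))
  adj0 <- adjust_pac_for_waveform(mi_null, wf)
  expect_gt(cor(adj0$adjusted, mi_null), 0.95)
  # constant feature column dropped with warning
  wf_bad <- wf; wf_bad$asym <- 1
  expect_warning(adj_b <- adjust_pac_for_waveform(mi_null, wf_bad),
                 "degenerate")
  expect_false("asym" %in% adj_b$report$set)
})

test_that("trial-level MI_Z is elevated under coupling", {
  ep1 <- make_lfp_epochs(30, window = c(0, 1400), buffer_ms = 600,
                         coupling_depth = 0.9, seed = 43, spacing_s = 2.7)
  z1 <- trial_mi_z(ep1$data, fs = 500, phase_freq = 5, amp_freq = 90,
                   buffer_ms = 600, n_surr = 60, seed = 2)
  ep0 <- make_lfp_epochs(30, window = c(0, 1400), buffer_ms = 600,
                         coupling_depth = 0, seed = 44, spacing_s = 2.7)
  z0 <- trial_mi_z(ep0$data, fs = 500, phase_freq = 5, amp_freq = 90,
                   buffer_ms = 600, n_surr = 60, seed = 2)
  expect_gt(mean(z1, na.rm = TRUE), mean(z0, na.rm = TRUE) + 0.5)
})
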