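# Generator contracts: spectral content, fixation statistics, gaze
# kinematics, on-disk round trips.

test_that("configuration invariants are enforced", {
  expect_error(sim_config(fs = 150, gamma_freq = 90), "fs must exceed")
  expect_error(sim_config(coupling_depth = 1.5), "coupling_depth")
  expect_error(sim_config(kappa_by_condition = c(Match = -1)), "kappa")
  expect_error(sim_config(p_remember = 2), "p_remember")
})

test_that("background spectral exponent is recovered from 120 s of signal", {
  cfg <- sim_config(duration_s = 120, aperiodic_exponent = 2,
                    theta_amp = 0, gamma_amp = 0, seed = 5)
  sim <- simulate_lfp(cfg)
  ps <- multitaper_psd(sim$recording$signal[1, ], fs = 500, fmin = 1,
                       fmax = 250)
  fit <- fit_spectral_model(ps, fit_range = c(2, 100))
  expect_equal(fit$exponent, 2, tolerance = 0.1)
})

test_that("theta component produces a 4-6 Hz spectral peak", {
  cfg <- sim_config(duration_s = 120, theta_amp = 1, gamma_amp = 0, seed = 6)
  sim <- simulate_lfp(cfg)
  ps <- multitaper_psd(sim$recording$signal[1, ], fs = 500, fmin = 1,
                       fmax = 30)
  in_band <- ps$freqs >= 4 & ps$freqs <= 6
  above <- ps$freqs > 6.5 & ps$freqs <= 10
  expect_gt(max(ps$power[in_band]), max(ps$power[above]))
})

test_that("ground-truth theta phase follows the package phase convention", {
  cfg <- sim_config(duration_s = 20, theta_freq_sd = 0, theta_amp = 1,
                    gamma_amp = 0, aperiodic_offset = -8, seed = 3)
  sim <- simulate_lfp(cfg)
  ep <- extract_epochs(sim$recording, c(5000, 9000), window = c(-750, 750),
                       buffer_ms = 1250)
  tf <- morlet_transform(ep, freqs = 5)
  i0 <- which.min(abs(tf$times_ms - 0))
  truth <- sim$truth$theta_phase[round(5 * 500) + 1]
  expect_equal(tf$phase[1, 1, i0], truth, tolerance = 0.05)
})

test_that("fixation count matches the nominal rate and durations >= 80 ms", {
  cfg <- sim_config(duration_s = 60, fixation_rate = 4, seed = 7)
  sim <- simulate_lfp(cfg)
  ev <- simulate_fixation_stream(cfg, sim$truth)
  expected <- 4 * 60
  bound <- stats::qpois(c(0.005, 0.995), expected)
  expect_gte(nrow(ev), bound[1])
  expect_lte(nrow(ev), bound[2])
  expect_true(all(ev$duration_ms >= 80))
})

test_that("fixation onset phases follow the programmed von Mises law", {
  # kappa = 0: Rayleigh non-significant in most runs
  set.seed(20)
  p_flat <- replicate(25, {
    cfg <- sim_config(duration_s = 30, fixation_rate = 3,
                      seed = sample.int(1e6, 1))
    sim <- simulate_lfp(cfg)
    rayleigh_test(attr(simulate_fixation_stream(cfg, sim$truth),
                       "phases"))$p
  })
  expect_gte(mean(p_flat > 0.05), 0.8)
  # kappa = 8 at phase 0: tight circular mean
  cfg8 <- sim_config(duration_s = 120, fixation_rate = 3,
                     kappa_by_condition = c(Match = 8, Mismatch = 8),
                     seed = 8)
  sim8 <- simulate_lfp(cfg8)
  ph <- attr(simulate_fixation_stream(cfg8, sim8$truth), "phases")
  expect_gte(length(ph), 300)
  expect_lt(abs(circ_mean(ph)$mean), 0.1)
})

test_that("gaze saccades exceed detection thresholds and parse back", {
  fix <- data.frame(onset_ms = c(200, 800, 1500),
                    duration_ms = c(400, 400, 400),
                    x = c(0, 5, 0), y = c(0, 0, 0))
  gaze <- make_scripted_gaze(fix, seed = 4)
  t <- gaze$time_ms / 1000
  v <- sqrt(diff(gaze$x_deg)^2 + diff(gaze$y_deg)^2) / diff(t)
  expect_gt(max(v), 100)
  parsed <- detect_eye_events(gaze)
  expect_equal(sum(parsed$kind == "saccade"), 2)
})

test_that("zero programmed saccades parse to exactly one fixation", {
  fix <- data.frame(onset_ms = 0, duration_ms = 2000, x = 1, y = 2)
  gaze <- make_scripted_gaze(fix, duration_s = 2, seed = 5)
  parsed <- detect_eye_events(gaze)
  expect_equal(nrow(parsed), 1)
  expect_equal(parsed$kind, "fixation")
})

test_that("datasets round-trip exactly and deterministically", {
  cfg <- sim_config(duration_s = 8, n_trials = 2, seed = 5)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  make_dataset(cfg, d1)
  make_dataset(cfg, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
  ds <- read_dataset(d1)
  sim <- simulate_lfp(cfg)
  rel <- abs(ds$recording$signal - sim$recording$signal) /
    pmax(abs(sim$recording$signal), 1e-12)
  expect_lt(max(rel), 1e-9)
  expect_identical(ds$trials$trial, sim$truth$trials$trial)
  # different seed -> different realization
  d3 <- withr::local_tempdir()
  make_dataset(sim_config(duration_s = 8, n_trials = 2, seed = 6), d3)
  expect_false(identical(readLines(file.path(d1, "signal.tsv")),
                         readLines(file.path(d3, "signal.tsv"))))
})
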