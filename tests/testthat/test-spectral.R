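# Morlet transform, multitaper PSD, spectral model, oscillation presence.

test_that("morlet transform tracks analytic phase and scales with power", {
  fs <- 500
  t <- seq(1 / fs, 8, by = 1 / fs)
  x <- matrix(cos(2 * pi * 5 * t + 0.7), 1)
  tf <- morlet_transform(x, freqs = log_freqs(30, 1, 10), fs = fs)
  mid <- 1000:3000
  # power maximal at the grid frequency nearest 5 Hz
  pk <- which.max(rowMeans(apply(tf$power[1, , mid], 1, identity)))
  pk <- which.max(apply(tf$power[1, , mid], 1, mean))
  expect_equal(tf$freqs[pk],
               tf$freqs[which.min(abs(tf$freqs - 5))])
  # unwrapped phase advances at 2*pi*5 per second
  i5 <- which.min(abs(tf$freqs - 5))
  dphase <- diff(tf$phase[1, i5, mid])
  dphase <- thetagaze:::wrap_pi(dphase)
  expect_equal(mean(dphase) * fs, 2 * pi * 5, tolerance = 0.05)
  # linearity: input x2 -> power x4, phase unchanged
  tf2 <- morlet_transform(2 * x, freqs = 5, fs = fs)
  tf1 <- morlet_transform(x, freqs = 5, fs = fs)
  expect_equal(tf2$power, 4 * tf1$power, tolerance = 1e-10)
  expect_equal(tf2$phase, tf1$phase, tolerance = 1e-10)
  # power invariant to phase offset of the sinusoid
  xoff <- matrix(cos(2 * pi * 5 * t + 2.1), 1)
  expect_equal(mean(morlet_transform(xoff, freqs = 5, fs = fs)$power[1, 1, mid]),
               mean(tf1$power[1, 1, mid]), tolerance = 0.01)
})

test_that("two-component signals show two power ridges", {
  fs <- 500
  t <- seq(1 / fs, 8, by = 1 / fs)
  x <- matrix(cos(2 * pi * 3 * t) + cos(2 * pi * 8 * t), 1)
  tf <- morlet_transform(x, freqs = log_freqs(30, 1, 10), fs = fs)
  prof <- apply(tf$power[1, , 1000:3000], 1, mean)
  locmax <- which(diff(sign(diff(prof))) == -2) + 1
  f_at <- sort(tf$freqs[locmax])
  expect_equal(length(f_at), 2)
  expect_equal(f_at[1], 3, tolerance = 0.3)
  expect_equal(f_at[2], 8, tolerance = 0.6)
})

test_that("multitaper PSD is flat for white noise and satisfies Parseval", {
  set.seed(21)
  x <- rnorm(32768)   # segment-averaged estimate tightens the slope
  ps <- multitaper_psd(x, fs = 500, fmin = 1, fmax = 250)
  sel <- ps$freqs >= 10 & ps$freqs <= 100
  slope <- stats::coef(stats::lm(log10(ps$power[sel]) ~
                                   log10(ps$freqs[sel])))[2]
  expect_lt(abs(slope), 0.1)
  # Parseval on a short epoch
  y <- rnorm(400)
  psy <- multitaper_psd(y, fs = 500, fmin = 0, fmax = 250)
  expect_equal(sum(psy$power) * 500 / 400, mean(y^2), tolerance = 0.05)
  # pure sinusoid peaks at its frequency
  t <- seq(1 / 500, 4, by = 1 / 500)
  pss <- multitaper_psd(sin(2 * pi * 20 * t), fs = 500, fmin = 1, fmax = 100)
  expect_equal(pss$freqs[which.max(pss$power)], 20, tolerance = 1.5)
  expect_error(multitaper_psd(y, fs = 500, fmax = 400), "Nyquist")
})

test_that("spectral model recovers exponents and peaks; F >= 1", {
  f <- seq(2, 100, length.out = 200)
  fit <- fit_spectral_model(list(freqs = f, power = 3 * f^-2))
  expect_equal(fit$exponent, 2, tolerance = 1e-6)
  expect_equal(nrow(fit$peaks), 0)
  expect_equal(fit$F, 1, tolerance = 1e-6)
  # gaussian bump at 5 Hz recovered
  lp <- log10(3 * f^-2) + 0.6 * exp(-(f - 5)^2 / (2 * 0.8^2))
  fit2 <- fit_spectral_model(list(freqs = f, power = 10^lp))
  expect_gte(nrow(fit2$peaks), 1)
  expect_equal(fit2$peaks$center[1], 5, tolerance = 0.5)
  expect_gt(fit2$F, 1)
  # flat spectrum -> exponent ~ 0
  fit3 <- fit_spectral_model(list(freqs = f, power = rep(2.5, 200)))
  expect_lt(abs(fit3$exponent), 0.01)
  expect_error(fit_spectral_model(list(freqs = f[1:10], power = f[1:10])),
               "20 frequency bins")
  expect_error(fit_spectral_model(list(freqs = f, power = rep(-1, 200))),
               "positive")
})

test_that("full spectral model never fits worse than aperiodic alone", {
  set.seed(22)
  for (i in 1:5) {
    f <- seq(2, 100, length.out = 150)
    p <- 10^(log10(f^-runif(1, 0.5, 2.5)) + rnorm(150, 0, 0.1))
    fit <- fit_spectral_model(list(freqs = f, power = p))
    expect_gte(fit$F, 1 - 1e-9)
    expect_lte(fit$resid_var_full, fit$resid_var_aperiodic + 1e-12)
  }
})

test_that("oscillation presence test detects theta and respects the null", {
  mk_ep <- function(theta_amp, n, seed) {
    make_lfp_epochs(n, window = c(-750, 50), theta_amp = theta_amp,
                    seed = seed)$data
  }
  r_on <- test_oscillation_presence(mk_ep(1, 60, 501), fs = 500,
                                    n_perm = 1000, seed = 1)
  expect_lt(r_on$p, 0.01)
  expect_gt(r_on$F, 1)
  p_off <- vapply(1:15, function(r) {
    test_oscillation_presence(mk_ep(0, 30, 600 + r), fs = 500,
                              n_perm = 500, seed = r)$p
  }, numeric(1))
  expect_lte(mean(p_off < 0.05), 0.2)
  expect_error(test_oscillation_presence(matrix(rnorm(800), 2), fs = 500),
               "10 fixation epochs")
})
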