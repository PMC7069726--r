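# Referencing, filtering, resampling, epoching.

make_two_channel <- function(fs = 1000, dur = 10, f1 = 5, f2 = 60) {
  t <- seq(1 / fs, dur, by = 1 / fs)
  x <- sin(2 * pi * f1 * t) + sin(2 * pi * f2 * t)
  continuous_recording(rbind(A1 = x, A2 = 0.5 * x), fs)
}

amp_at <- function(x, f, fs) {
  n <- length(x)
  2 * Mod(stats::fft(x))[round(f * n / fs) + 1] / n
}

test_that("bipolar referencing subtracts pairs and propagates exclusions", {
  rec <- make_two_channel()
  bp <- bipolar_reference(rec, list(c("A1", "A2")))
  expect_equal(bp$labels, "A1-A2")
  expect_equal(bp$signal[1, ], rec$signal[1, ] - rec$signal[2, ])
  # identical channels -> zero; constant offset -> constant
  recc <- continuous_recording(rbind(B1 = rec$signal[1, ],
                                     B2 = rec$signal[1, ] + 3), 1000)
  z <- bipolar_reference(recc, list(c("B1", "B1"), c("B2", "B1")))
  expect_true(all(z$signal[1, ] == 0))
  expect_equal(unname(z$signal[2, ]), rep(3, ncol(z$signal)),
               tolerance = 1e-12)
  # antisymmetry
  neg <- bipolar_reference(rec, list(c("A2", "A1")))
  expect_equal(neg$signal[1, ], -bp$signal[1, ])
  expect_error(bipolar_reference(rec, list(c("A1", "ZZ"))), "unknown")
  rec$exclude["A2"] <- TRUE
  expect_true(bipolar_reference(rec, list(c("A1", "A2")))$exclude[[1]])
})

test_that("notch filter attenuates line noise, passes theta, zero phase", {
  rec <- make_two_channel()
  nf <- notch_filter(rec, 60)
  expect_gt(20 * log10(amp_at(rec$signal[1, ], 60, 1000) /
                         amp_at(nf$signal[1, ], 60, 1000)), 20)
  expect_equal(amp_at(nf$signal[1, ], 5, 1000),
               amp_at(rec$signal[1, ], 5, 1000), tolerance = 0.01)
  # zero signal in, zero out
  z <- continuous_recording(matrix(0, 1, 5000), 1000)
  expect_true(all(notch_filter(z, 60)$signal == 0))
  expect_error(notch_filter(rec, 600), "Nyquist")
  # zero-phase: cross-correlation peak at zero lag for the 5 Hz component
  cc <- stats::ccf(nf$signal[1, ], rec$signal[1, ], lag.max = 20,
                   plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
})

test_that("resampling preserves passband amplitude and rejects upsampling", {
  rec <- make_two_channel(f2 = 30)
  rs <- resample_recording(rec, 500)
  expect_equal(ncol(rs$signal), 5000)
  expect_equal(amp_at(rs$signal[1, ], 5, 500), 1, tolerance = 0.01)
  # content above the target Nyquist is strongly attenuated
  t <- seq(1e-3, 10, by = 1e-3)
  hi <- continuous_recording(matrix(sin(2 * pi * 300 * t), 1), 1000)
  hs <- resample_recording(hi, 500)
  expect_lt(sqrt(mean(hs$signal^2)) / sqrt(mean(hi$signal^2)), 0.1)
  expect_identical(resample_recording(rec, 1000), rec)
  expect_error(resample_recording(rec, 2000), "upsampling")
})

test_that("preprocessing is linear in the input", {
  rec <- make_two_channel()
  a <- 3.7
  scaled <- continuous_recording(a * rec$signal, rec$fs, rec$labels)
  expect_equal(notch_filter(scaled, 60)$signal,
               a * notch_filter(rec, 60)$signal, tolerance = 1e-5)
  expect_equal(resample_recording(scaled, 500)$signal,
               a * resample_recording(rec, 500)$signal, tolerance = 1e-5)
})

test_that("epoch extraction honors windows, buffers and boundary drops", {
  rec <- continuous_recording(matrix(seq_len(30000), 1), 500)
  ep <- extract_epochs(rec, c(100, 5000, 10000, 59000),
                       window = c(-750, 750), buffer_ms = 1250)
  # first onset too close to the start, last beyond the recording: dropped
  expect_equal(nrow(ep$data), 2)
  dropped <- attr(ep, "dropped")
  expect_equal(dropped$onset_ms, c(100, 59000))
  # length contract
  expect_equal(ncol(ep$data), round((1500 + 2 * 1250) * 500 / 1000) + 1)
  # constant signal -> identical constant epochs
  recc <- continuous_recording(matrix(2.5, 1, 10000), 500)
  epc <- extract_epochs(recc, c(5000, 8000), window = c(-100, 100),
                        buffer_ms = 200)
  expect_true(all(epc$data == 2.5))
  expect_error(extract_epochs(rec, 10, window = c(-750, 750),
                              buffer_ms = 1250), "zero surviving")
})
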