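# Cluster permutation inference, binomial proportions, effect sizes.

make_itc_maps <- function(inject, seed, n_sub = 5, n_events = 100,
                          kappa = 0.62) {
  freqs <- log_freqs(30, 1, 10)
  times <- seq(0, 500, by = 10)
  reg <- outer(freqs >= 4 & freqs <= 6, times >= 100 & times <= 300, "&")
  set.seed(seed)
  arr <- function(locked) {
    out <- array(0, c(n_sub, length(freqs), length(times)))
    for (s in seq_len(n_sub)) {
      for (j in seq_along(freqs)) for (k in seq_along(times)) {
        ph <- if (locked && reg[j, k]) rvonmises(n_events, 0, kappa) else
          runif(n_events, -pi, pi)
        out[s, j, k] <- itc(ph)$itc
      }
    }
    out
  }
  list(a = arr(inject), b = arr(FALSE), region = reg)
}

test_that("cluster test finds no clusters for identical conditions", {
  set.seed(61)
  x <- array(rnorm(5 * 10 * 12), c(5, 10, 12))
  cl <- cluster_permutation_test(x, x, tail = "two", n_perm = 200, seed = 1)
  expect_equal(length(cl$mass), 0)
})

test_that("blocked sign-flip null calibrates the FWE rate", {
  # small maps for speed; 60 null runs
  set.seed(62)
  rej <- vapply(1:60, function(r) {
    a <- array(rnorm(5 * 12 * 15), c(5, 12, 15))
    b <- array(rnorm(5 * 12 * 15), c(5, 12, 15))
    any(cluster_permutation_test(a, b, tail = "one", n_perm = 500,
                                 seed = r)$p_fwe < 0.05)
  }, logical(1))
  expect_gte(mean(rej), 0.0)
  expect_lte(mean(rej), 0.12)
})

test_that("injected time-frequency effects are localized by the clusters", {
  m <- make_itc_maps(TRUE, 63)
  cl <- cluster_permutation_test(m$a, m$b, tail = "one", n_perm = 500,
                                 seed = 3)
  sig <- which(cl$p_fwe < 0.05)
  expect_gte(length(sig), 1)
  covered <- Reduce(`|`, cl$masks[sig])
  expect_gte(sum(covered & m$region) / sum(m$region), 0.8)
  # masks are connected components
  for (k in sig) {
    lab <- thetagaze:::label_components(cl$masks[[k]])
    expect_equal(max(lab), 1)
  }
})

test_that("p_fwe never drops below the permutation resolution", {
  m <- make_itc_maps(TRUE, 64, n_sub = 4)
  cl <- cluster_permutation_test(m$a, m$b, tail = "one", n_perm = 500,
                                 seed = 4)
  expect_true(all(cl$p_fwe >= 1 / 2^4))
  expect_true(all(cl$p_fwe <= 1))
})

test_that("binomial proportion test matches closed forms", {
  expect_equal(binomial_proportion_test(0, 32), 1)
  expect_equal(binomial_proportion_test(32, 32), 0.05^32)
  # direct summation oracle for 11 of 32
  oracle <- sum(vapply(11:32, function(k) {
    choose(32, k) * 0.05^k * 0.95^(32 - k)
  }, numeric(1)))
  expect_equal(binomial_proportion_test(11, 32), oracle, tolerance = 1e-12)
  expect_error(binomial_proportion_test(1, 0), "positive")
  expect_error(binomial_proportion_test(5, 3), "n_sig")
})

test_that("dependent-samples Hedges g matches hand evaluation", {
  expect_equal(hedges_g_dependent(c(1, 2, 3), c(1, 2, 3))$g, 0)
  # differences {1, 2, 3}: d = 2, J = 1 - 3/7
  g <- hedges_g_dependent(c(2, 4, 6), c(1, 2, 3))
  expect_equal(g$g, 2 * (1 - 3 / 7), tolerance = 1e-12)
  expect_equal(g$J, 4 / 7)
  # constant nonzero differences: undefined, flagged
  und <- hedges_g_dependent(c(2, 3, 4), c(1, 2, 3))
  expect_false(und$defined)
  expect_true(is.na(und$g))
})

test_that("permutation p is invariant to condition relabeling (two-tailed)", {
  set.seed(65)
  a <- array(rnorm(5 * 8 * 8, 0.1), c(5, 8, 8))
  b <- array(rnorm(5 * 8 * 8), c(5, 8, 8))
  cl_ab <- cluster_permutation_test(a, b, tail = "two", n_perm = 500, seed = 9)
  cl_ba <- cluster_permutation_test(b, a, tail = "two", n_perm = 500, seed = 9)
  expect_equal(sort(cl_ab$p_fwe), sort(cl_ba$p_fwe))
  expect_equal(sort(abs(cl_ab$mass)), sort(abs(cl_ba$mass)))
})
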