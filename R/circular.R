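# Circular statistics: resultant-based summaries, Rayleigh and
# Watson-Williams tests, von Mises sampling. Phase convention throughout the
# package: radians in (-pi, pi], 0 = oscillation peak, +/-pi = trough.

#' Circular mean and resultant length
#' @param angles numeric vector of angles (radians).
#' @return list with `mean` (radians in (-pi, pi]) and `r` (resultant length
#'   in \[0, 1\]).
#' @export
circ_mean <- function(angles) {
  check(length(angles) >= 1 && all(is.finite(angles)), "angles must be finite")
  z <- mean(exp(1i * angles))
  list(mean = Arg(z), r = Mod(z))
}

#' Circular mean with a dispersion-based 95% confidence interval
#'
#' The CI uses the circular dispersion \eqn{\delta = (1 - \rho_2) / (2 R^2)}
#' (Fisher 1993), giving a standard error \eqn{\sqrt{\delta / n}} for the mean
#' direction. When the resultant length is very small (`r < 0.1`) the
#' asymptotic CI is unreliable and a percentile bootstrap (1000 resamples) is
#' used instead; if the mean direction is essentially undefined the CI is
#' flagged.
#'
#' @param angles numeric vector of angles (radians), length >= 3.
#' @param conf confidence level (default 0.95).
#' @param boot_n bootstrap resamples used in the small-R fallback.
#' @return list with `mean`, `r`, `ci` (lo, hi radians), `n`, and
#'   `ci_defined` (FALSE when the resultant is too small to orient a CI).
#' @export
circular_mean_ci <- function(angles, conf = 0.95, boot_n = 1000) {
  n <- length(angles)
  check(n >= 3, "need at least 3 angles")
  cm <- circ_mean(angles)
  mu <- cm$mean
  r <- cm$r
  if (r < 1e-8) {
    return(list(mean = mu, r = r, ci = c(NA_real_, NA_real_), n = n,
                ci_defined = FALSE))
  }
  zq <- stats::qnorm(1 - (1 - conf) / 2)
  if (r >= 0.1) {
    rho2 <- Mod(mean(exp(2i * angles)))
    delta <- (1 - rho2) / (2 * r^2)
    se <- sqrt(delta / n)
    if (zq * se >= 1) {
      return(list(mean = mu, r = r, ci = c(NA_real_, NA_real_), n = n,
                  ci_defined = FALSE))
    }
    half <- asin(zq * se)
  } else {
    mus <- vapply(seq_len(boot_n), function(i) {
      circ_mean(angles[sample.int(n, n, replace = TRUE)])$mean
    }, numeric(1))
    dev <- abs(wrap_pi(mus - mu))
    half <- stats::quantile(dev, conf, names = FALSE)
  }
  list(mean = mu, r = r, ci = wrap_pi(c(mu - half, mu + half)), n = n,
       ci_defined = TRUE)
}

#' Rayleigh test for circular uniformity
#'
#' Z = n R^2 with the standard large-sample p approximation
#' (Zar 1999, eq. 27.4).
#'
#' @param angles numeric vector of angles (radians), n >= 5.
#' @return list with `Z`, `p`, `n`, `r`.
#' @export
rayleigh_test <- function(angles) {
  n <- length(angles)
  check(n >= 5, "Rayleigh test needs n >= 5")
  r <- circ_mean(angles)$r
  Z <- n * r^2
  p <- exp(-Z) * (1 + (2 * Z - Z^2) / (4 * n) -
                    (24 * Z - 132 * Z^2 + 76 * Z^3 - 9 * Z^4) / (288 * n^2))
  list(Z = Z, p = max(min(p, 1), 0), n = n, r = r)
}

# Maximum-likelihood-style estimate of the von Mises concentration from a
# resultant length (Fisher 1993 approximations).
kappa_from_r <- function(r) {
  if (r < 0.53) {
    2 * r + r^3 + 5 * r^5 / 6
  } else if (r < 0.85) {
    -0.4 + 1.39 * r + 0.43 / (1 - r)
  } else {
    1 / (r^3 - 4 * r^2 + 3 * r)
  }
}

#' Watson-Williams two-sample test for equal mean directions
#'
#' Parametric F statistic with the standard concentration correction
#' factor; assumes comparable, moderately concentrated samples. Use
#' [watson_williams_perm()] for inference free of those assumptions.
#'
#' @param a,b numeric vectors of angles (radians), each n >= 5.
#' @return list with `F`, `df1`, `df2`, `p_param`, `kappa`.
#' @export
watson_williams <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  check(n1 >= 5 && n2 >= 5, "Watson-Williams needs n >= 5 per sample")
  n <- n1 + n2
  R1 <- n1 * circ_mean(a)$r
  R2 <- n2 * circ_mean(b)$r
  R <- n * circ_mean(c(a, b))$r
  rw <- (R1 + R2) / n
  check(rw > 1e-6, "degenerate samples: zero resultant")
  kap <- kappa_from_r(rw)
  K <- 1 + 3 / (8 * kap)
  Fstat <- K * ((n - 2) * (R1 + R2 - R)) / (n - R1 - R2)
  Fstat <- max(Fstat, 0)
  p <- stats::pf(Fstat, 1, n - 2, lower.tail = FALSE)
  list(F = Fstat, df1 = 1, df2 = n - 2, p_param = p, kappa = kap)
}

#' Permutation Watson-Williams test
#'
#' Observed Watson-Williams F, a permutation null built by shuffling group
#' labels, a standardized effect `Z_F = (F_obs - mean(null)) / sd(null)`, and
#' the null exceedance proportion as p-value.
#'
#' @param a,b numeric vectors of angles (radians).
#' @param n_perm number of label permutations (default 1000).
#' @param seed integer seed for the permutation stream.
#' @return list with `F`, `Z_F`, `p`, `n_perm`, plus the parametric fields.
#' @export
watson_williams_perm <- function(a, b, n_perm = 1000, seed = 1) {
  obs <- watson_williams(a, b)
  pool <- c(a, b)
  n1 <- length(a)
  n <- length(pool)
  set.seed(seed)
  null_F <- vapply(seq_len(n_perm), function(i) {
    idx <- sample.int(n, n1)
    f <- tryCatch(watson_williams(pool[idx], pool[-idx])$F,
                  error = function(e) NA_real_)
    f
  }, numeric(1))
  null_F <- null_F[is.finite(null_F)]
  check(length(null_F) >= 10, "too few valid permutations")
  z <- (obs$F - mean(null_F)) / stats::sd(null_F)
  p <- (1 + sum(null_F >= obs$F)) / (length(null_F) + 1)
  c(obs, list(Z_F = z, p = p, n_perm = length(null_F)))
}

#' Sample from a von Mises distribution
#'
#' Best-Fisher (1979) rejection algorithm; reduces to uniform sampling at
#' kappa = 0.
#'
#' @param n number of draws.
#' @param mu mean direction (radians).
#' @param kappa concentration, >= 0.
#' @return numeric vector of angles in (-pi, pi].
#' @export
rvonmises <- function(n, mu = 0, kappa = 1) {
  check(kappa >= 0, "kappa must be >= 0")
  if (kappa < 1e-8) return(wrap_pi(stats::runif(n, -pi, pi)))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u <- stats::runif(3)
    z <- cos(pi * u[1])
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    if (cc * (2 - cc) - u[2] > 0 || log(cc / u[2]) + 1 - cc >= 0) {
      out[i] <- sign(u[3] - 0.5) * acos(f)
      i <- i + 1L
    }
  }
  wrap_pi(out + mu)
}
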