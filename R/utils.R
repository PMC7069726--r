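# Internal numeric helpers shared across modules.

#' Wrap angles into (-pi, pi]
#' @param x numeric vector of angles in radians.
#' @return angles wrapped into (-pi, pi].
#' @keywords internal
wrap_pi <- function(x) {
  y <- (x + pi) %% (2 * pi) - pi
  # %% maps exact pi to -pi; keep the (-pi, pi] convention
  y[y == -pi] <- pi
  y
}

#' Analytic signal via the FFT method
#'
#' Returns the complex analytic signal whose real part is `x` and whose
#' imaginary part is the Hilbert transform of `x`.
#'
#' @param x real numeric vector.
#' @return complex vector, same length as `x`.
#' @keywords internal
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

# Seed helper: derive a stream-specific seed from a base seed without
# exceeding .Machine$integer.max.
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 7919 + k * 104729) %% 2147483629L)
}

# Stop unless condition holds; terse contract checks.
check <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
}
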