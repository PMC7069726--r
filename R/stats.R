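# Nonparametric cluster-based permutation inference over time(-frequency)
# maps, electrode-proportion binomial tests, and dependent-samples effect
# size. Family-wise error is controlled by the max-cluster-mass null:
# per-bin cluster-forming thresholds come from the permutation null itself
# (95th percentile one-tailed, 2.5th/97.5th two-tailed), clusters are
# connected components (4-connectivity in frequency x time, 2-connectivity
# along a 1-D axis), and each observed cluster's summed statistic is referred
# to the distribution of the maximum cluster mass across permutations.

# Label connected components of a logical mask. Vector input: runs of TRUE.
# Matrix input: 4-connected components (iterative flood fill).
label_components <- function(mask) {
  if (is.vector(mask)) {
    lab <- integer(length(mask))
    r <- rle(mask)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    k <- 0L
    for (i in seq_along(r$values)) {
      if (r$values[i]) {
        k <- k + 1L
        lab[starts[i]:ends[i]] <- k
      }
    }
    return(lab)
  }
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  k <- 0L
  idx <- which(mask)
  for (s in idx) {
    if (lab[s] != 0L) next
    k <- k + 1L
    queue <- s
    lab[s] <- k
    while (length(queue)) {
      cur <- queue[length(queue)]
      queue <- queue[-length(queue)]
      i <- (cur - 1L) %% nr + 1L
      j <- (cur - 1L) %/% nr + 1L
      nb <- c(if (i > 1) cur - 1L, if (i < nr) cur + 1L,
              if (j > 1) cur - nr, if (j < nc) cur + nr)
      for (q in nb) {
        if (mask[q] && lab[q] == 0L) {
          lab[q] <- k
          queue <- c(queue, q)
        }
      }
    }
  }
  lab
}

# Sum the statistic within each labelled component; returns named vector.
component_masses <- function(stat, lab) {
  ks <- setdiff(unique(as.vector(lab)), 0L)
  if (!length(ks)) return(numeric(0))
  vapply(sort(ks), function(k) sum(stat[lab == k]), numeric(1))
}

#' Cluster inference from an observed map and precomputed null maps
#'
#' Shared back end for all cluster tests: thresholds, component labelling,
#' and the max-cluster-mass FWE correction.
#'
#' @param stat_obs observed statistic (vector for 1-D, matrix freq x time).
#' @param null_stats matrix n_perm x n_bins of null statistics (bins in the
#'   same order as `as.vector(stat_obs)`).
#' @param tail `"one"` (positive) or `"two"`.
#' @param exact TRUE when `null_stats` enumerates the complete permutation
#'   group (including the identity): p-values are then exact proportions
#'   without the add-one correction.
#' @return list of class `cluster_result`: `masks` (list of logical masks in
#'   the shape of `stat_obs`), `mass`, `p_fwe`, `n_perm`, `tail`,
#'   `threshold_hi`, `threshold_lo`.
#' @export
cluster_from_null <- function(stat_obs, null_stats, tail = c("one", "two"),
                              exact = FALSE) {
  tail <- match.arg(tail)
  dims <- dim(stat_obs)
  v_obs <- as.vector(stat_obs)
  n_perm <- nrow(null_stats)
  if (tail == "one") {
    thr_hi <- apply(null_stats, 2, stats::quantile, 0.95, names = FALSE)
    thr_lo <- rep(-Inf, length(v_obs))
  } else {
    thr_hi <- apply(null_stats, 2, stats::quantile, 0.975, names = FALSE)
    thr_lo <- apply(null_stats, 2, stats::quantile, 0.025, names = FALSE)
  }
  shape <- function(v) if (is.null(dims)) v else matrix(v, dims[1], dims[2])

  masses_of <- function(v) {
    out <- numeric(0)
    labs <- list()
    m_hi <- shape(v > thr_hi)
    lab_hi <- label_components(m_hi)
    mh <- component_masses(shape(v), lab_hi)
    if (tail == "two") {
      m_lo <- shape(v < thr_lo)
      lab_lo <- label_components(m_lo)
      ml <- component_masses(shape(v), lab_lo)
    } else ml <- numeric(0)
    list(hi = mh, lo = ml, lab_hi = lab_hi,
         lab_lo = if (tail == "two") lab_lo else NULL)
  }

  obs <- masses_of(v_obs)
  null_max <- vapply(seq_len(n_perm), function(b) {
    mm <- masses_of(null_stats[b, ])
    cand <- c(mm$hi, -mm$lo)
    if (length(cand)) max(cand) else 0
  }, numeric(1))

  masks <- list(); mass <- numeric(0)
  add_clusters <- function(lab) {
    ks <- setdiff(unique(as.vector(lab)), 0L)
    for (k in sort(ks)) {
      masks[[length(masks) + 1]] <<- (lab == k)
      mass <<- c(mass, sum(shape(v_obs)[lab == k]))
    }
  }
  add_clusters(obs$lab_hi)
  if (tail == "two") add_clusters(obs$lab_lo)
  p_fwe <- vapply(mass, function(m) {
    if (exact) mean(null_max >= abs(m)) else
      (1 + sum(null_max >= abs(m))) / (n_perm + 1)
  }, numeric(1))
  structure(list(masks = masks, mass = mass, p_fwe = p_fwe, n_perm = n_perm,
                 tail = tail, threshold_hi = shape(thr_hi),
                 threshold_lo = shape(thr_lo)),
            class = "cluster_result")
}

#' Cluster-based permutation test for a paired condition contrast
#'
#' Units (subjects or electrodes) each contribute a map per condition; the
#' per-bin statistic is the mean within-unit difference, and the null is
#' built by flipping each unit's condition labels (permutation blocked at
#' the unit level, so observations are never exchanged across units). When
#' the complete sign-flip group is no larger than `n_perm` (2^units), it is
#' enumerated exactly and p-values are exact permutation proportions;
#' otherwise `n_perm` random flips are drawn.
#'
#' @param x,y arrays: units x freqs x time (or units x time matrices, or
#'   units x bins), paired by unit, same shape.
#' @param tail `"one"` tests x > y; `"two"` is two-sided.
#' @param n_perm number of sign-flip permutations (default 1000; < 100
#'   triggers a warning).
#' @param seed RNG seed.
#' @return a `cluster_result` (see [cluster_from_null()]), plus elements
#'   `stat` (observed mean difference map) and `n_units`.
#' @export
cluster_permutation_test <- function(x, y, tail = c("one", "two"),
                                     n_perm = 1000, seed = 1) {
  tail <- match.arg(tail)
  if (n_perm < 100) warning("n_perm < 100 gives a very coarse p-value")
  dx <- dim(x)
  check(!is.null(dx) && all(dx == dim(y)), "x and y must be equal-shape arrays")
  n_units <- dx[1]
  check(n_units >= 2, "need at least 2 units")
  map_dims <- if (length(dx) == 3) dx[2:3] else NULL
  D <- matrix(as.vector(x) - as.vector(y), nrow = n_units)
  if (any(!is.finite(D))) stop("non-finite values in condition maps")
  obs_v <- colMeans(D)
  exact <- n_units <= 20 && 2^n_units <= n_perm
  if (exact) {
    S <- as.matrix(expand.grid(rep(list(c(-1, 1)), n_units)))
    n_perm <- nrow(S)
  } else {
    set.seed(seed)
    S <- matrix(sample(c(-1, 1), n_perm * n_units, replace = TRUE),
                n_perm, n_units)
  }
  null_stats <- (S %*% D) / n_units
  stat_obs <- if (is.null(map_dims)) obs_v else
    matrix(obs_v, map_dims[1], map_dims[2])
  res <- cluster_from_null(stat_obs, null_stats, tail = tail, exact = exact)
  res$stat <- stat_obs
  res$n_units <- n_units
  res
}

#' Upper-tail binomial test for the proportion of significant electrodes
#'
#' P(X >= n_sig) for X ~ Binomial(n_total, p0); the observation is included
#' in the tail. Bonferroni multipliers across conditions/time periods are the
#' caller's responsibility.
#'
#' @param n_sig number of significant electrodes.
#' @param n_total total electrodes (> 0).
#' @param p0 chance rate (default 0.05).
#' @return upper-tail p-value.
#' @export
binomial_proportion_test <- function(n_sig, n_total, p0 = 0.05) {
  check(n_total > 0, "n_total must be positive")
  check(n_sig >= 0 && n_sig <= n_total, "n_sig must be in [0, n_total]")
  stats::pbinom(n_sig - 1, n_total, p0, lower.tail = FALSE)
}

#' Hedges' g for dependent (paired) samples
#'
#' g = (mean(x - y) / sd(x - y)) * J with the small-sample correction
#' J = 1 - 3 / (4 (n - 1) - 1).
#'
#' @param x,y paired numeric vectors, equal length n >= 2.
#' @return list: `g`, `n`, `J`, `defined` (FALSE when sd of differences is
#'   zero, in which case `g` is NA).
#' @export
hedges_g_dependent <- function(x, y) {
  n <- length(x)
  check(n == length(y) && n >= 2, "x and y must be paired with n >= 2")
  d <- x - y
  s <- stats::sd(d)
  J <- 1 - 3 / (4 * (n - 1) - 1)
  if (s == 0) {
    if (all(d == 0)) return(list(g = 0, n = n, J = J, defined = TRUE))
    return(list(g = NA_real_, n = n, J = J, defined = FALSE))
  }
  list(g = mean(d) / s * J, n = n, J = J, defined = TRUE)
}
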