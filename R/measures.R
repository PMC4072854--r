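# ---- input validation helpers -----------------------------------------------

.check_profile <- function(x, name = deparse(substitute(x)), min_len = 2L) {
  if (!is.numeric(x)) {
    stop(sprintf("'%s' must be a numeric vector", name), call. = FALSE)
  }
  if (length(x) < min_len) {
    stop(sprintf("'%s' must have length >= %d", name, min_len), call. = FALSE)
  }
  if (any(!is.finite(x))) {
    stop(sprintf("'%s' contains non-finite values", name), call. = FALSE)
  }
  invisible(x)
}

.check_pair <- function(x, y, min_len = 2L) {
  .check_profile(x, "x", min_len)
  .check_profile(y, "y", min_len)
  if (length(x) != length(y)) {
    stop("'x' and 'y' must have equal length", call. = FALSE)
  }
  invisible(NULL)
}

.check_timestamps <- function(t, n) {
  if (!is.numeric(t) || any(!is.finite(t))) {
    stop("timestamps must be a finite numeric vector", call. = FALSE)
  }
  if (length(t) != n) {
    stop("timestamps must have the same length as the profiles", call. = FALSE)
  }
  if (any(diff(t) <= 0)) {
    stop("timestamps must be strictly increasing", call. = FALSE)
  }
  invisible(t)
}

# Degenerate-value policy: constant (or zero-norm) profiles make a correlation
# undefined; clustering of real expression matrices must not abort on flat
# profiles, so the correlation is reported as 0 with a warning.
.degenerate_cor <- function(what) {
  warning(sprintf("degenerate input in %s; returning 0", what), call. = FALSE)
  0
}

# ---- rank transform ---------------------------------------------------------

#' Rank transform of an expression profile
#'
#' Replaces values by their ranks, assigning tied values the average of the
#' ranks they span (fractional ranks). This is the rank convention used by
#' every rank-based measure in the package.
#'
#' @param x Numeric vector (finite, length >= 2).
#' @return Numeric vector of ranks in `[1, length(x)]`; ranks always sum to
#'   `n(n+1)/2`.
#' @examples
#' rank_transform(c(3, 1, 4, 1))  # 3, 1.5, 4, 1.5
#' @export
rank_transform <- function(x) {
  .check_profile(x, "x", min_len = 1L)
  rank(x, ties.method = "average")
}

# ---- correlation coefficients -----------------------------------------------

#' Pearson correlation with a degenerate-input policy
#'
#' Standard product-moment correlation. A constant profile leaves the
#' correlation undefined; the package convention returns 0 with a warning so
#' that flat expression profiles do not abort a clustering run.
#'
#' @param x,y Numeric profiles of equal length.
#' @return Correlation in `[-1, 1]`.
#' @export
pearson_cor <- function(x, y) {
  .check_pair(x, y)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(.degenerate_cor("pearson_cor"))
  }
  r <- stats::cor(x, y)
  # guard against rounding just outside [-1, 1]
  max(-1, min(1, r))
}

#' Spearman rank correlation
#'
#' Pearson correlation applied to the fractional ranks of both profiles.
#' Invariant under strictly increasing transforms of either argument.
#'
#' @inheritParams pearson_cor
#' @return Correlation in `[-1, 1]`.
#' @export
spearman_cor <- function(x, y) {
  .check_pair(x, y)
  rx <- rank_transform(x)
  ry <- rank_transform(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    return(.degenerate_cor("spearman_cor"))
  }
  max(-1, min(1, stats::cor(rx, ry)))
}

#' Concordant, discordant and neutral pair counts
#'
#' Classifies all `n(n-1)/2` index pairs of two profiles: concordant pairs
#' keep the same strict order in both profiles, discordant pairs reverse it,
#' and pairs tied in either profile are neutral. These counts are the basis
#' of the Goodman-Kruskal and Kendall coefficients.
#'
#' @inheritParams pearson_cor
#' @return Named numeric vector with elements `concordant`, `discordant`,
#'   `neutral`; the three always sum to `n(n-1)/2`.
#' @export
count_pairs <- function(x, y) {
  .check_pair(x, y)
  dx <- sign(outer(x, x, "-"))
  dy <- sign(outer(y, y, "-"))
  up <- upper.tri(dx)
  prod_sign <- dx[up] * dy[up]
  conc <- sum(prod_sign > 0)
  disc <- sum(prod_sign < 0)
  n <- length(x)
  c(concordant = conc, discordant = disc,
    neutral = n * (n - 1) / 2 - conc - disc)
}

#' Goodman-Kruskal gamma correlation
#'
#' `(P+ - P-) / (P+ + P-)` over concordant and discordant pairs; neutral
#' pairs are ignored, so gamma reaches +/-1 as soon as all untied pairs agree
#' (or disagree). If every pair is neutral the value is undefined and the
#' degenerate policy (0 with a warning) applies.
#'
#' @inheritParams pearson_cor
#' @return Correlation in `[-1, 1]`.
#' @export
goodman_kruskal <- function(x, y) {
  p <- count_pairs(x, y)
  denom <- p[["concordant"]] + p[["discordant"]]
  if (denom == 0) {
    return(.degenerate_cor("goodman_kruskal"))
  }
  (p[["concordant"]] - p[["discordant"]]) / denom
}

#' Kendall tau-a correlation
#'
#' `(P+ - P-) / (n(n-1)/2)`: the same pair counts as Goodman-Kruskal but
#' normalised by the total number of pairs (tau-a). With neutral (tied) pairs
#' present the magnitude cannot reach 1; in particular `kendall_tau(x, x) < 1`
#' when `x` has ties. This tau-a form is deliberate (it is the printed
#' definition this package follows), not the tie-corrected tau-b.
#'
#' @inheritParams pearson_cor
#' @return Correlation in `[-1, 1]`.
#' @export
kendall_tau <- function(x, y) {
  p <- count_pairs(x, y)
  n <- length(x)
  (p[["concordant"]] - p[["discordant"]]) / (n * (n - 1) / 2)
}

#' Asymmetric Rank-Magnitude correlation
#'
#' Correlates the ranks of `x` with the magnitudes of `y`:
#' `(2 * sum(Rank(x_i) * y_i) - maxrank - minrank) / (maxrank - minrank)`
#' where, with `y` sorted increasingly, `minrank = sum(y_(i) * (n - i + 1))`
#' and `maxrank = sum(i * y_(i))`. Equals 1 when the ranks of `x` order `y`
#' perfectly increasingly and -1 on perfect reversal. Constant `y` makes the
#' denominator vanish; the degenerate policy applies.
#'
#' @inheritParams pearson_cor
#' @return Value in `[-1, 1]`.
#' @export
rank_magnitude_asym <- function(x, y) {
  .check_pair(x, y)
  n <- length(x)
  ys <- sort(y)               # stable ascending
  minrank <- sum(ys * (n - seq_len(n) + 1))
  maxrank <- sum(seq_len(n) * ys)
  if (maxrank == minrank) {
    return(.degenerate_cor("rank_magnitude_asym"))
  }
  (2 * sum(rank_transform(x) * y) - maxrank - minrank) / (maxrank - minrank)
}

#' Symmetric Rank-Magnitude correlation
#'
#' The symmetrised Rank-Magnitude coefficient
#' `RM(x, y) = (r(x, y) + r(y, x)) / 2`, averaging the two asymmetric
#' directions so that both rank behaviour and magnitudes of the two profiles
#' enter the value.
#'
#' @inheritParams pearson_cor
#' @return Correlation in `[-1, 1]`, symmetric in its arguments.
#' @export
rank_magnitude <- function(x, y) {
  (rank_magnitude_asym(x, y) + rank_magnitude_asym(y, x)) / 2
}

#' Weighted Goodman-Kruskal correlation
#'
#' A magnitude-weighted variant of Goodman-Kruskal. For each pair `(i, j)`
#' the signed percentage differences
#' `wx = (x_i - x_j) / (max(x) - min(x))` and `wy` likewise are formed
#' (0 for a constant profile). A pair contributes to the numerator:
#' `min(wx/wy, wy/wx)` if concordant (`wx * wy > 0`, a value in `(0, 1]`),
#' `max(wx/wy, wy/wx)` if discordant (in `[-1, 0)`), 1 if both differences
#' are zero, and 0 if exactly one is zero. The denominator counts pairs that
#' are untied in both profiles plus double-tied pairs, so that
#' `WGK(x, x) = 1` and the value stays in `[-1, 1]`.
#'
#' @inheritParams pearson_cor
#' @return Correlation in `[-1, 1]`.
#' @export
weighted_goodman_kruskal <- function(x, y) {
  .check_pair(x, y)
  n <- length(x)
  rng_x <- max(x) - min(x)
  rng_y <- max(y) - min(y)
  ij <- which(upper.tri(diag(n)), arr.ind = TRUE)
  dxx <- x[ij[, 1]] - x[ij[, 2]]
  dyy <- y[ij[, 1]] - y[ij[, 2]]
  wx <- if (rng_x == 0) rep(0, nrow(ij)) else dxx / rng_x
  wy <- if (rng_y == 0) rep(0, nrow(ij)) else dyy / rng_y

  num <- numeric(nrow(ij))
  both_zero <- wx == 0 & wy == 0
  conc <- wx * wy > 0
  disc <- wx * wy < 0
  num[both_zero] <- 1
  num[conc] <- pmin(wx[conc] / wy[conc], wy[conc] / wx[conc])
  num[disc] <- pmax(wx[disc] / wy[disc], wy[disc] / wx[disc])

  denom_count <- sum(conc | disc | both_zero)
  if (denom_count == 0) {
    return(.degenerate_cor("weighted_goodman_kruskal"))
  }
  sum(num) / denom_count
}

# ---- traditional distances --------------------------------------------------

#' Minkowski distance family
#'
#' `(sum |x_i - y_i|^lambda)^(1/lambda)`. `lambda = 1` is Manhattan,
#' `lambda = 2` Euclidean and `lambda = Inf` the supremum (Chebyshev)
#' distance.
#'
#' @inheritParams pearson_cor
#' @param lambda Exponent, `>= 1` or `Inf`.
#' @return Nonnegative distance.
#' @export
minkowski_dist <- function(x, y, lambda = 2) {
  .check_pair(x, y)
  if (!is.numeric(lambda) || length(lambda) != 1 || is.na(lambda) || lambda < 1) {
    stop("'lambda' must be a single number >= 1 (or Inf)", call. = FALSE)
  }
  d <- abs(x - y)
  if (is.infinite(lambda)) max(d) else sum(d^lambda)^(1 / lambda)
}

#' Cosine distance
#'
#' One minus the cosine of the angle between the two profiles (taken from
#' the origin, unlike Pearson which centres first). Lies in `[0, 2]`.
#' A zero-norm profile leaves the angle undefined: the similarity is then
#' reported as 0 (distance 1) with a warning.
#'
#' @inheritParams pearson_cor
#' @return Distance in `[0, 2]`.
#' @export
cosine_dist <- function(x, y) {
  .check_pair(x, y)
  nx <- sqrt(sum(x^2))
  ny <- sqrt(sum(y^2))
  if (nx == 0 || ny == 0) {
    return(1 - .degenerate_cor("cosine_dist"))
  }
  sim <- sum(x * y) / (nx * ny)
  1 - max(-1, min(1, sim))
}

# ---- jackknife --------------------------------------------------------------

#' Jackknife correlation
#'
#' The minimum Pearson correlation over the full profiles and every
#' leave-one-feature-out copy (the same feature removed from both profiles).
#' A single outlier that inflates Pearson is removed in one of the
#' leave-one-out terms, so `JK(x, y) <= PE(x, y)` always.
#'
#' @inheritParams pearson_cor
#' @param incremental If `TRUE`, use O(n) sufficient-statistic updates
#'   (subtracting each point's contribution from the five running sums)
#'   instead of recomputing each leave-one-out Pearson from scratch.
#'   Both paths agree to 1e-10 and the incremental one is the default for
#'   long cancer-style profiles.
#' @return Correlation in `[-1, 1]`.
#' @export
jackknife_cor <- function(x, y, incremental = length(x) > 100) {
  .check_pair(x, y, min_len = 3L)
  if (!incremental) {
    vals <- vapply(seq_along(x), function(i) {
      pearson_cor(x[-i], y[-i])
    }, numeric(1))
    return(min(pearson_cor(x, y), vals))
  }
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  sxx <- sum(x^2); syy <- sum(y^2); sxy <- sum(x * y)
  pe_from_sums <- function(n, sx, sy, sxx, syy, sxy) {
    vx <- sxx - sx^2 / n
    vy <- syy - sy^2 / n
    if (vx <= 0 || vy <= 0) return(.degenerate_cor("jackknife_cor"))
    max(-1, min(1, (sxy - sx * sy / n) / sqrt(vx * vy)))
  }
  best <- pe_from_sums(n, sx, sy, sxx, syy, sxy)
  for (i in seq_len(n)) {
    v <- pe_from_sums(n - 1, sx - x[i], sy - y[i],
                      sxx - x[i]^2, syy - y[i]^2, sxy - x[i] * y[i])
    if (v < best) best <- v
  }
  best
}

# ---- conversion -------------------------------------------------------------

#' Convert a correlation to a clustering distance
#'
#' `d = 1 - r`, mapping `[-1, 1]` onto `[0, 2]`. The sign of the correlation
#' matters for expression data, so anti-correlated profiles are maximally
#' distant.
#'
#' @param r Correlation value(s) in `[-1, 1]`.
#' @return Distance value(s) in `[0, 2]`.
#' @export
corr_to_dist <- function(r) {
  if (any(!is.finite(r)) || any(r < -1 - 1e-12) || any(r > 1 + 1e-12)) {
    stop("correlation values must lie in [-1, 1]", call. = FALSE)
  }
  1 - pmin(1, pmax(-1, r))
}
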