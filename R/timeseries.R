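# Measures tailored for short gene time-series. Profiles are genes measured
# at n timepoints t_1 < ... < t_n; all slope-based quantities normalise by
# the interval length so non-uniform sampling is handled.

.slopes <- function(a, t) {
  diff(a) / diff(t)
}

#' Short Time-Series (STS) dissimilarity
#'
#' Euclidean norm of the difference between the timestamp-normalised slope
#' sequences of the two series:
#' `sqrt(sum_i ((y_{i+1}-y_i)/(t_{i+1}-t_i) - (x_{i+1}-x_i)/(t_{i+1}-t_i))^2)`.
#' Shorter sampling intervals therefore weigh more. Zero iff the two slope
#' sequences coincide; adding a constant to either series leaves the value
#' unchanged.
#'
#' @param x,y Numeric profiles of equal length (>= 2).
#' @param t Strictly increasing timestamps, same length as the profiles.
#' @return Nonnegative dissimilarity.
#' @export
sts_dist <- function(x, y, t) {
  .check_pair(x, y)
  .check_timestamps(t, length(x))
  sqrt(sum((.slopes(y, t) - .slopes(x, t))^2))
}

#' Slope-sign agreement A
#'
#' Fraction of the `n - 1` intervals on which the two series move in the
#' same direction (slope sign in `{-1, 0, +1}` compared exactly).
#'
#' @inheritParams sts_dist
#' @return Agreement in `[0, 1]`.
#' @export
slope_agreement <- function(x, y, t) {
  .check_pair(x, y)
  .check_timestamps(t, length(x))
  mean(sign(.slopes(x, t)) == sign(.slopes(y, t)))
}

#' Extremum-position agreement M
#'
#' 1 if the two series attain their maximum at the same timepoint and their
#' minimum at the same timepoint, 0.5 if exactly one of the two extrema
#' coincides, 0 otherwise. Ties for an extremum are resolved by first
#' occurrence.
#'
#' @param x,y Numeric profiles of equal length.
#' @return One of 0, 0.5, 1.
#' @export
extremum_agreement <- function(x, y) {
  .check_pair(x, y)
  max_agree <- which.max(x) == which.max(y)
  min_agree <- which.min(x) == which.min(y)
  (max_agree + min_agree) / 2
}

.check_theta <- function(theta) {
  if (length(theta) != 3 || any(theta < 0) || abs(sum(theta) - 1) > 1e-9) {
    stop("'theta' must be three nonnegative weights summing to 1",
         call. = FALSE)
  }
  invisible(theta)
}

#' YS1 similarity
#'
#' Weighted combination `theta1 * A + theta2 * M + theta3 * S` of slope-sign
#' agreement ([slope_agreement]), extremum-position agreement
#' ([extremum_agreement]) and the rescaled Spearman correlation
#' `S = (1 + SP(x, y)) / 2`. With convex weights the value lies in `[0, 1]`;
#' the distance used for clustering is `1 - YS1`.
#'
#' @inheritParams sts_dist
#' @param theta Weights `(theta1, theta2, theta3)`, default `(1/4, 1/4, 1/2)`.
#' @return Similarity in `[0, 1]`.
#' @export
ys1_sim <- function(x, y, t, theta = c(0.25, 0.25, 0.5)) {
  .check_theta(theta)
  a <- slope_agreement(x, y, t)
  m <- extremum_agreement(x, y)
  s <- (1 + spearman_cor(x, y)) / 2
  theta[1] * a + theta[2] * m + theta[3] * s
}

#' YR1 similarity
#'
#' As [ys1_sim] but with the rescaled Pearson correlation
#' `R = (1 + PE(x, y)) / 2` in place of Spearman.
#'
#' @inheritParams ys1_sim
#' @return Similarity in `[0, 1]`.
#' @export
yr1_sim <- function(x, y, t, theta = c(0.25, 0.25, 0.5)) {
  .check_theta(theta)
  a <- slope_agreement(x, y, t)
  m <- extremum_agreement(x, y)
  r <- (1 + pearson_cor(x, y)) / 2
  theta[1] * a + theta[2] * m + theta[3] * r
}

# ---- LSS --------------------------------------------------------------------

# Null distribution of Spearman's rho for untied samples of size k, as the
# exact permutation distribution (k! values, memoized). Used to calibrate
# window scores so that shorter windows, where large rho is likelier by
# chance, are penalised.
.spearman_null_env <- new.env(parent = emptyenv())

.spearman_null <- function(k) {
  key <- as.character(k)
  if (!is.null(.spearman_null_env[[key]])) return(.spearman_null_env[[key]])
  perms <- function(v) {
    if (length(v) == 1) return(matrix(v, 1, 1))
    out <- NULL
    for (i in seq_along(v)) {
      rest <- perms(v[-i])
      out <- rbind(out, cbind(v[i], rest))
    }
    out
  }
  p <- perms(seq_len(k))
  id <- seq_len(k)
  rho <- apply(p, 1, function(pr) {
    1 - 6 * sum((pr - id)^2) / (k * (k^2 - 1))
  })
  res <- sort(rho)
  .spearman_null_env[[key]] <- res
  res
}

#' Probability-calibrated Spearman window score
#'
#' Score `S(x, y) = 1 - p` where `p` is the upper-tail probability of
#' observing a Spearman correlation at least as large as the one between the
#' two equal-length windows, under the null of random ordering. For window
#' length `k <= 7` the exact permutation distribution of rho is enumerated;
#' for larger `k` the t-approximation
#' `t = rho * sqrt((k - 2) / (1 - rho^2))` on `k - 2` degrees of freedom is
#' used. Ties inside a window are ranked fractionally and scored against the
#' tie-free null (a documented approximation).
#'
#' @param x,y Equal-length numeric windows (length >= 2).
#' @return Score in `[0, 1)`; higher means a stronger, less probable
#'   positive rank agreement.
#' @export
lss_window_score <- function(x, y) {
  .check_pair(x, y)
  k <- length(x)
  rx <- rank_transform(x)
  ry <- rank_transform(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    rho <- 0
  } else {
    rho <- max(-1, min(1, stats::cor(rx, ry)))
  }
  if (k <= 7) {
    null <- .spearman_null(k)
    p <- mean(null >= rho - 1e-12)
  } else {
    if (abs(rho) >= 1) {
      p <- if (rho > 0) 0 else 1
    } else {
      tt <- rho * sqrt((k - 2) / (1 - rho^2))
      p <- stats::pt(tt, df = k - 2, lower.tail = FALSE)
    }
  }
  1 - p
}

#' Local Shape-based Similarity (LSS)
#'
#' Seeks the best local, possibly time-shifted (transposed), alignment
#' between two series: over window lengths `k` from `min_k` to `n` and all
#' offset pairs `(i, j)`, the maximum probability-calibrated Spearman score
#' ([lss_window_score]) of the two length-`k` windows
#' `x[i..i+k-1]` and `y[j..j+k-1]`. The default `min_k = n - 2` follows the
#' measure's original recommendation. The distance used for clustering is
#' `1 - LSS`.
#'
#' @param x,y Numeric profiles of equal length `n >= 3`.
#' @param min_k Minimum window length, `2 <= min_k <= n`; default `n - 2`.
#' @return Similarity in `[0, 1)`.
#' @export
lss_sim <- function(x, y, min_k = length(x) - 2L) {
  .check_pair(x, y, min_len = 3L)
  n <- length(x)
  min_k <- as.integer(min_k)
  if (min_k < 2L || min_k > n) {
    stop("'min_k' must satisfy 2 <= min_k <= length(x)", call. = FALSE)
  }
  best <- -Inf
  for (k in min_k:n) {
    for (i in seq_len(n + 1 - k)) {
      xi <- x[i:(i + k - 1)]
      for (j in seq_len(n + 1 - k)) {
        s <- lss_window_score(xi, y[j:(j + k - 1)])
        if (s > best) best <- s
      }
    }
  }
  best
}
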