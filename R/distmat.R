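# Distance-matrix construction: one of 15 measures applied to every object
# pair of a dataset. Correlations and similarities are converted to
# distances (d = 1 - r); the Minkowski family is used as-is.

#' The 15 supported measure identifiers
#'
#' Correlation coefficients: `PE` (Pearson), `GK` (Goodman-Kruskal), `SP`
#' (Spearman), `KE` (Kendall tau-a), `WGK` (Weighted Goodman-Kruskal), `RM`
#' (symmetric Rank-Magnitude). Traditional distances: `COS` (cosine), `EUC`,
#' `MAN`, `SUP` (Minkowski with lambda 2, 1, Inf). Short time-series
#' measures: `JK` (Jackknife), `STS`, `LSS`, `YS1`, `YR1`.
#'
#' @return Character vector of the 15 identifiers.
#' @export
measure_ids <- function() {
  c("PE", "GK", "SP", "KE", "WGK", "RM", "COS", "EUC", "MAN", "SUP",
    "JK", "STS", "LSS", "YS1", "YR1")
}

.needs_timestamps <- function(measure) measure %in% c("STS", "YS1", "YR1")

# scalar distance between two profiles under a named measure
.measure_fun <- function(measure, t = NULL, theta = c(0.25, 0.25, 0.5),
                         min_k = NULL) {
  switch(measure,
    PE  = function(x, y) corr_to_dist(pearson_cor(x, y)),
    GK  = function(x, y) corr_to_dist(goodman_kruskal(x, y)),
    SP  = function(x, y) corr_to_dist(spearman_cor(x, y)),
    KE  = function(x, y) corr_to_dist(kendall_tau(x, y)),
    WGK = function(x, y) corr_to_dist(weighted_goodman_kruskal(x, y)),
    RM  = function(x, y) corr_to_dist(rank_magnitude(x, y)),
    COS = function(x, y) cosine_dist(x, y),
    EUC = function(x, y) minkowski_dist(x, y, 2),
    MAN = function(x, y) minkowski_dist(x, y, 1),
    SUP = function(x, y) minkowski_dist(x, y, Inf),
    JK  = function(x, y) corr_to_dist(jackknife_cor(x, y)),
    STS = function(x, y) sts_dist(x, y, t),
    LSS = function(x, y) {
      mk <- if (is.null(min_k)) length(x) - 2L else min_k
      1 - lss_sim(x, y, min_k = mk)
    },
    YS1 = function(x, y) 1 - ys1_sim(x, y, t, theta),
    YR1 = function(x, y) 1 - yr1_sim(x, y, t, theta),
    stop(sprintf("unknown measure '%s'; see measure_ids()", measure),
         call. = FALSE)
  )
}

#' Pairwise distance matrix under one of the 15 measures
#'
#' Builds the symmetric objects-by-objects distance matrix that the
#' clustering methods consume. Correlation measures are converted with
#' `d = 1 - r`. The diagonal is the self-distance under the measure: zero
#' everywhere except for Kendall tau-a on profiles with ties, where
#' `KE(x, x) < 1` by construction (tau-a keeps the full-pair denominator),
#' so the self-distance is honestly positive.
#'
#' @param data An `expr_dataset`, or a plain numeric matrix (objects in
#'   rows).
#' @param measure One of [measure_ids()].
#' @param theta YS1/YR1 weights, default `c(1/4, 1/4, 1/2)`.
#' @param min_k LSS minimum window length; default `n_features - 2`.
#' @param unit_spacing_fallback If `TRUE`, a time-series measure requested
#'   on a dataset without timestamps uses unit spacing `1..n`; otherwise
#'   this is an error (silent unit spacing would change STS values).
#' @return A `distmat` object: symmetric numeric matrix with object ids as
#'   dimnames and the measure id as attribute `measure`.
#' @export
distance_matrix <- function(data, measure, theta = c(0.25, 0.25, 0.5),
                            min_k = NULL, unit_spacing_fallback = FALSE) {
  if (inherits(data, "expr_dataset")) {
    m <- data$mat
    t <- data$timestamps
  } else if (is.matrix(data) && is.numeric(data)) {
    m <- data
    t <- NULL
    if (is.null(rownames(m))) rownames(m) <- sprintf("obj%d", seq_len(nrow(m)))
  } else {
    stop("'data' must be an expr_dataset or numeric matrix", call. = FALSE)
  }
  measure <- match.arg(measure, measure_ids())
  if (.needs_timestamps(measure) && is.null(t)) {
    if (!unit_spacing_fallback) {
      stop(sprintf("measure '%s' requires timestamps (or set unit_spacing_fallback = TRUE)",
                   measure), call. = FALSE)
    }
    t <- seq_len(ncol(m))
  }
  n <- nrow(m)

  D <- switch(measure,
    EUC = as.matrix(stats::dist(m, method = "euclidean")),
    MAN = as.matrix(stats::dist(m, method = "manhattan")),
    SUP = as.matrix(stats::dist(m, method = "maximum")),
    {
      f <- .measure_fun(measure, t = t, min_k = min_k, theta = theta)
      D <- matrix(0, n, n)
      for (i in seq_len(n)) {
        for (j in i:n) {
          if (j == i && !(measure %in% c("KE"))) next  # exact zero diagonal
          d <- f(m[i, ], m[j, ])
          D[i, j] <- d
          D[j, i] <- d
        }
      }
      D
    }
  )
  dimnames(D) <- list(rownames(m), rownames(m))
  structure(D, measure = measure, class = c("distmat", "matrix", "array"))
}

#' @export
print.distmat <- function(x, ...) {
  cat(sprintf("distance matrix (%s): %d objects\n",
              attr(x, "measure"), nrow(x)))
  print(unclass(x)[seq_len(min(6, nrow(x))), seq_len(min(6, ncol(x)))])
  if (nrow(x) > 6) cat("...\n")
  invisible(x)
}

#' Coerce a distmat to a stats "dist" object (lower triangle)
#' @param m A `distmat`.
#' @return A `dist` object suitable for [stats::hclust].
#' @export
as_dist <- function(m) {
  stats::as.dist(unclass(m))
}

#' Write a distance matrix as a full square TSV
#'
#' Object ids appear as first row and first column; values are printed with
#' 12 significant digits so the file reads back to the stored entries.
#'
#' @param D A `distmat` or square numeric matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_distmat_tsv <- function(D, path) {
  out <- cbind(id = rownames(D), apply(unclass(D), 2, .fmt_num))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a distance matrix written by [write_distmat_tsv]
#' @param path Path to the TSV file.
#' @param measure Optional measure id to record on the result.
#' @return A `distmat`.
#' @export
read_distmat_tsv <- function(path, measure = NA_character_) {
  raw <- utils::read.delim(path, header = TRUE, row.names = 1,
                           check.names = FALSE)
  D <- as.matrix(raw)
  if (nrow(D) != ncol(D)) {
    stop("distance matrix file is not square", call. = FALSE)
  }
  structure(D, measure = measure, class = c("distmat", "matrix", "array"))
}
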