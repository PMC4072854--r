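# Synthetic labelled data in the two regimes the benchmarking scenarios
# need: (a) sample-clustering matrices (samples x genes, k planted sample
# clusters: cluster-specific mean profiles plus i.i.d. Gaussian noise) in
# the dimension range of published cancer compendia (tens-hundreds of
# samples, hundreds-thousands of genes); (b) short gene time-series
# (genes x timepoints, 7-24 timepoints, ~1000 genes) with planted shape
# clusters and per-gene offsets; plus GMT gene sets aligned with the
# planted gene clusters.

#' Generate a labelled sample-clustering dataset
#'
#' Each of the `k` clusters receives a mean profile drawn as
#' `separation * N(0, 1)` per gene; each sample is its cluster mean plus
#' i.i.d. `N(0, sd^2)` noise. The ratio `separation / sd` therefore
#' controls recoverability of the planted partition.
#'
#' @param n_objects Number of samples (default 60).
#' @param n_features Number of genes (default 500).
#' @param k Number of planted clusters (default 3).
#' @param proportions Cluster proportions summing to 1 (default equal);
#'   realised sizes differ from `n_objects * proportions` by at most one
#'   object.
#' @param separation Standard deviation of cluster mean profiles
#'   (default 1).
#' @param sd Within-cluster noise standard deviation (default 0.2).
#' @param seed RNG seed; output is deterministic given it.
#' @return An `expr_dataset` with `labels` set to the planted partition.
#' @export
gen_sample_dataset <- function(n_objects = 60, n_features = 500, k = 3,
                               proportions = rep(1 / k, k),
                               separation = 1, sd = 0.2, seed = 1) {
  if (k > n_objects) stop("'k' must not exceed 'n_objects'", call. = FALSE)
  if (length(proportions) != k || any(proportions <= 0) ||
      abs(sum(proportions) - 1) > 1e-9) {
    stop("'proportions' must be k positive values summing to 1",
         call. = FALSE)
  }
  if (separation <= 0 || sd < 0) {
    stop("'separation' must be > 0 and 'sd' >= 0", call. = FALSE)
  }
  .with_seed(seed, {
    sizes <- .apportion(n_objects, proportions)
    labels <- rep(seq_len(k), sizes)
    means <- matrix(stats::rnorm(k * n_features, sd = separation),
                    k, n_features)
    mat <- means[labels, , drop = FALSE] +
      matrix(stats::rnorm(n_objects * n_features, sd = sd),
             n_objects, n_features)
    rownames(mat) <- sprintf("sample%d", seq_len(n_objects))
    colnames(mat) <- sprintf("gene%d", seq_len(n_features))
    expression_dataset(mat, labels = labels)
  })
}

# largest-remainder apportionment of n into round(n * p) sizes
.apportion <- function(n, p) {
  raw <- n * p
  sizes <- floor(raw)
  rem <- n - sum(sizes)
  if (rem > 0) {
    extra <- order(raw - sizes, decreasing = TRUE)[seq_len(rem)]
    sizes[extra] <- sizes[extra] + 1
  }
  as.integer(sizes)
}

# fixed, documented shape templates on normalised time s in [0, 1]
.shape_templates <- list(
  up      = function(s) 2 * s - 1,                # monotone increase
  down    = function(s) 1 - 2 * s,                # monotone decrease
  peak    = function(s) 1 - 8 * (s - 0.5)^2,      # single maximum mid-way
  trough  = function(s) 8 * (s - 0.5)^2 - 1,      # single minimum mid-way
  cyclic  = function(s) sin(2 * pi * s)           # one full period
)

#' Generate a labelled short gene time-series dataset
#'
#' Each planted cluster follows one of five fixed shape templates (monotone
#' up, monotone down, single peak, single trough, one sinusoid period)
#' evaluated at the timestamps, with unit amplitude. Every gene is its
#' cluster's template plus i.i.d. `N(0, sd^2)` noise plus a per-gene
#' constant offset drawn uniformly on `[-offset_range, offset_range]`.
#' The offsets separate magnitude- from shape-driven measures: rank and
#' slope measures are unaffected while magnitude distances inflate.
#'
#' @param n_genes Number of genes (default 1000, matching the scale of the
#'   yeast stress/cell-cycle compendia this emulates).
#' @param n_timepoints Number of timepoints (default 10; the short-series
#'   regime is 7-24).
#' @param timestamps Optional strictly increasing vector; default uniform
#'   `0, 1, ..., n_timepoints - 1`.
#' @param k Number of planted shape clusters (2-5, default 4: the first
#'   `k` templates are used).
#' @param sd Noise standard deviation (default 0.1, i.e. 10% of the unit
#'   template amplitude).
#' @param offset_range Half-width of the uniform per-gene offset
#'   (default 2).
#' @param seed RNG seed.
#' @return An `expr_dataset` (genes as objects) with `timestamps` and
#'   planted `labels`.
#' @export
gen_timeseries_dataset <- function(n_genes = 1000, n_timepoints = 10,
                                   timestamps = NULL, k = 4, sd = 0.1,
                                   offset_range = 2, seed = 1) {
  if (n_timepoints < 3) stop("'n_timepoints' must be >= 3", call. = FALSE)
  if (k < 1 || k > length(.shape_templates)) {
    stop(sprintf("'k' must be between 1 and %d", length(.shape_templates)),
         call. = FALSE)
  }
  if (is.null(timestamps)) timestamps <- seq_len(n_timepoints) - 1
  .check_timestamps(timestamps, n_timepoints)
  s <- (timestamps - min(timestamps)) / (max(timestamps) - min(timestamps))
  .with_seed(seed, {
    sizes <- .apportion(n_genes, rep(1 / k, k))
    labels <- rep(seq_len(k), sizes)
    templ <- vapply(.shape_templates[seq_len(k)], function(f) f(s),
                    numeric(n_timepoints))
    mat <- t(templ)[labels, , drop = FALSE] +
      matrix(stats::rnorm(n_genes * n_timepoints, sd = sd),
             n_genes, n_timepoints) +
      stats::runif(n_genes, -offset_range, offset_range)
    rownames(mat) <- sprintf("gene%d", seq_len(n_genes))
    colnames(mat) <- sprintf("t%d", seq_len(n_timepoints))
    expression_dataset(mat, timestamps = timestamps, labels = labels)
  })
}

#' Generate gene sets aligned with planted gene clusters
#'
#' For each planted cluster, `n_terms_per_cluster` gene sets are drawn.
#' A fraction `purity` of each set's members comes from the matching
#' cluster, the remainder uniformly from the other clusters, so enrichment
#' of a recovered partition against these sets is calibrated: at
#' `purity = 1` the matching cluster's hypergeometric p-value takes its
#' closed-form minimum, while purity at the background rate gives no
#' enrichment in expectation.
#'
#' @param labels Named partition vector over genes (e.g. the planted labels
#'   of [gen_timeseries_dataset]).
#' @param n_terms_per_cluster Sets drawn per cluster (default 2).
#' @param set_size Genes per set (default 20, capped at cluster size for
#'   the within-cluster part).
#' @param purity Fraction of each set drawn from the matching cluster, in
#'   `(0, 1]` (default 1).
#' @param seed RNG seed.
#' @return Named list of character vectors (GMT-ready, see [write_gmt]).
#' @export
gen_annotation <- function(labels, n_terms_per_cluster = 2, set_size = 20,
                           purity = 1, seed = 1) {
  if (is.null(names(labels))) {
    stop("'labels' must be named by gene id", call. = FALSE)
  }
  if (purity <= 0 || purity > 1) {
    stop("'purity' must be in (0, 1]", call. = FALSE)
  }
  genes <- names(labels)
  .with_seed(seed, {
    sets <- list()
    for (cl in sort(unique(labels))) {
      members <- genes[labels == cl]
      others <- genes[labels != cl]
      for (tm in seq_len(n_terms_per_cluster)) {
        n_in <- min(round(purity * set_size), length(members))
        n_out <- min(set_size - n_in, length(others))
        nm <- sprintf("SET_C%s_T%d", cl, tm)
        sets[[nm]] <- c(sample(members, n_in),
                        if (n_out > 0) sample(others, n_out))
      }
    }
    sets
  })
}
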