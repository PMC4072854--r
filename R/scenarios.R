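# The four evaluation scenarios: fixed number of clusters, best ARI over a
# k-interval, Silhouette-estimated number of clusters, and robustness to
# noise injection; plus the wins/ties/losses aggregation used when results
# are compared pairwise by enrichment.

.scenario_distmat <- function(data, measure, ...) {
  distance_matrix(data, measure, ...)
}

.reference_k <- function(data) {
  k <- n_classes(data)
  if (k < 2) {
    stop("reference partition must have at least 2 classes", call. = FALSE)
  }
  k
}

#' Fixed-number-of-clusters scenario
#'
#' Clusters the dataset into exactly as many clusters as the reference
#' partition defines and scores the result by Adjusted Rand Index against
#' the reference.
#'
#' @param data A labelled `expr_dataset`.
#' @param measure One of [measure_ids()].
#' @param method `"AL"`, `"CL"`, `"SL"` or `"KM"`.
#' @param restarts,seed Passed to [kmedoids] for `method = "KM"`.
#' @param ... Passed to [distance_matrix].
#' @return List with `ari`, `k` and the `partition`.
#' @export
scenario_fixed_k <- function(data, measure, method = "AL",
                             restarts = 50, seed = 1, ...) {
  k <- .reference_k(data)
  D <- .scenario_distmat(data, measure, ...)
  p <- cluster_distmat(D, method, k, restarts = restarts, seed = seed)
  list(ari = adjusted_rand(p, data$labels), k = k, partition = p)
}

.default_k_range <- function(n, k_max = 50) {
  2:min(n - 1, k_max)
}

#' Best-ARI-over-k scenario
#'
#' Sweeps the number of clusters over `k_range` (default the interval
#' `[2, o]` capped -- see Details) and returns the best ARI against the
#' reference regardless of k. By construction the score is at least the
#' fixed-k score whenever the reference k lies in the range.
#'
#' Details: the canonical interval is `[2, o]` with `o` the number of
#' objects; the default caps it at `min(o - 1, k_max)` to keep sweeps with
#' 50-restart k-medoids tractable. Pass `k_range = 2:(n - 1)` explicitly
#' for the uncapped interval.
#'
#' @inheritParams scenario_fixed_k
#' @param k_range Integer vector of cluster numbers to try.
#' @return List with `best_ari`, `best_k`, and the per-k ARI vector `ari`.
#' @export
scenario_best_k <- function(data, measure, method = "AL",
                            k_range = NULL, restarts = 50, seed = 1, ...) {
  stopifnot(!is.null(data$labels))
  D <- .scenario_distmat(data, measure, ...)
  n <- nrow(D)
  if (is.null(k_range)) k_range <- .default_k_range(n)
  aris <- vapply(k_range, function(k) {
    p <- cluster_distmat(D, method, k, restarts = restarts, seed = seed)
    adjusted_rand(p, data$labels)
  }, numeric(1))
  best <- which.max(aris)
  list(best_ari = aris[best], best_k = k_range[best],
       ari = stats::setNames(aris, k_range))
}

#' Silhouette-estimated-number-of-clusters scenario
#'
#' Simulates the unsupervised setting: for every k in `k_range` the data
#' is clustered and the partition with the largest mean Silhouette width
#' is selected (ties: smallest k). Reference labels are never read during
#' selection; if the dataset carries labels, the selected partition is
#' additionally validated by ARI afterwards.
#'
#' @inheritParams scenario_best_k
#' @return List with `k` (selected), `silhouette` (its width),
#'   `partition`, `ari` (`NA` when the dataset has no labels), and the
#'   per-k silhouette vector `silhouettes`.
#' @export
scenario_estimated_k <- function(data, measure, method = "AL",
                                 k_range = NULL, restarts = 50, seed = 1,
                                 ...) {
  D <- .scenario_distmat(data, measure, ...)
  n <- nrow(D)
  if (is.null(k_range)) k_range <- .default_k_range(n)
  parts <- lapply(k_range, function(k) {
    cluster_distmat(D, method, k, restarts = restarts, seed = seed)
  })
  sil <- vapply(parts, function(p) silhouette_width(D, p), numeric(1))
  if (all(is.na(sil))) {
    stop("silhouette not evaluable for any k in range", call. = FALSE)
  }
  best <- which(sil == max(sil, na.rm = TRUE))[1]  # ties: smallest k
  ari <- if (!is.null(data$labels)) {
    adjusted_rand(parts[[best]], data$labels)
  } else NA_real_
  list(k = k_range[best], silhouette = sil[best],
       partition = parts[[best]], ari = ari,
       silhouettes = stats::setNames(sil, k_range))
}

#' Inject uniform noise into an expression matrix
#'
#' Chooses `round(alpha / 100 * n_cells)` distinct cells at random (without
#' replacement; round-half-to-even) and replaces each with a value drawn
#' uniformly between the global minimum and maximum of the original
#' matrix.
#'
#' @param data An `expr_dataset`.
#' @param alpha Percentage of cells to perturb, in `[0, 100]`.
#' @param seed RNG seed; deterministic given it.
#' @return A new `expr_dataset` with the same ids, timestamps and labels.
#' @export
inject_noise <- function(data, alpha, seed = 1) {
  stopifnot(inherits(data, "expr_dataset"))
  if (!is.numeric(alpha) || alpha < 0 || alpha > 100) {
    stop("'alpha' must be a percentage in [0, 100]", call. = FALSE)
  }
  m <- data$mat
  n_cells <- length(m)
  n_noise <- round(alpha / 100 * n_cells)
  if (n_noise > 0) {
    lo <- min(m)
    hi <- max(m)
    m <- .with_seed(seed, {
      cells <- sample.int(n_cells, n_noise)
      m[cells] <- stats::runif(n_noise, lo, hi)
      m
    })
  }
  expression_dataset(m, timestamps = data$timestamps,
                     labels = data$labels)
}

#' Robustness-to-noise scenario
#'
#' For each noise level in `alpha_grid` and each of `replicates` noisy
#' copies of the dataset (child seed derived from the base seed per
#' (level, replicate) so every level is independently reproducible), runs
#' the fixed-k scenario and reports the mean and standard deviation of the
#' ARI per (measure, level).
#'
#' @param data A labelled `expr_dataset`.
#' @param measures Character vector of measure ids.
#' @param method Clustering method id.
#' @param alpha_grid Noise percentages (default `1:20`).
#' @param replicates Noisy datasets per level (default 100).
#' @param seed Base seed.
#' @param restarts k-medoids restarts.
#' @param ... Passed to [distance_matrix].
#' @return Data frame with columns `measure`, `alpha`, `mean_ari`,
#'   `sd_ari`.
#' @export
scenario_noise <- function(data, measures, method = "AL",
                           alpha_grid = 1:20, replicates = 100, seed = 1,
                           restarts = 50, ...) {
  stopifnot(!is.null(data$labels), replicates >= 1)
  k <- .reference_k(data)
  out <- list()
  for (meas in measures) {
    for (ai in seq_along(alpha_grid)) {
      alpha <- alpha_grid[ai]
      aris <- vapply(seq_len(replicates), function(rep) {
        child <- seed + 10000L * ai + rep
        noisy <- inject_noise(data, alpha, seed = child)
        D <- distance_matrix(noisy, meas, ...)
        p <- cluster_distmat(D, method, k, restarts = restarts,
                             seed = child)
        adjusted_rand(p, data$labels)
      }, numeric(1))
      out[[length(out) + 1]] <- data.frame(
        measure = meas, alpha = alpha,
        mean_ari = mean(aris), sd_ari = stats::sd(aris)
      )
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# ---- wins / ties / losses ---------------------------------------------------

#' Pairwise comparisons per method-pair cell
#'
#' With `m` distance measures and `d` datasets, comparing two clustering
#' methods means comparing every (measure, measure) combination on every
#' dataset: `m * m * d` pairwise comparisons per cell.
#'
#' @param n_measures Number of distance measures.
#' @param n_datasets Number of datasets.
#' @return Integer comparison count.
#' @export
comparisons_per_cell <- function(n_measures, n_datasets) {
  as.integer(n_measures) * as.integer(n_measures) * as.integer(n_datasets)
}

#' Wins/ties/losses matrix between clustering methods
#'
#' Input is a nested list `results[[method]][[measure]][[dataset]]` of
#' enrichment lists (p-value vectors or [fisher_enrichment] data frames).
#' For every ordered method pair (A, B), every measure pair and every
#' dataset, the two enrichment lists are compared with
#' [compare_enrichments]; a positive score is a win for A, zero a tie,
#' negative a loss. Every cell therefore holds
#' `n_measures^2 * n_datasets` comparisons, and the win matrix entry
#' (A, B) equals the loss entry (B, A).
#'
#' @param results Nested list as described; all methods must share the
#'   same measure and dataset names.
#' @return List of square matrices `wins`, `ties`, `losses` and the scalar
#'   `comparisons_per_cell`.
#' @export
wins_ties_losses <- function(results) {
  methods <- names(results)
  if (length(methods) < 2) stop("need at least two methods", call. = FALSE)
  measures <- names(results[[1]])
  datasets <- names(results[[1]][[1]])
  for (m in methods) {
    if (!identical(names(results[[m]]), measures)) {
      stop(sprintf("method '%s' is missing measures from the grid", m),
           call. = FALSE)
    }
    for (mm in measures) {
      if (!identical(names(results[[m]][[mm]]), datasets)) {
        stop(sprintf("cell (%s, %s) is missing datasets", m, mm),
             call. = FALSE)
      }
    }
  }
  nm <- length(methods)
  W <- T_ <- L <- matrix(0L, nm, nm, dimnames = list(methods, methods))
  for (a in methods) {
    for (b in methods) {
      if (a == b) next
      w <- t_ <- l <- 0L
      for (ma in measures) {
        for (mb in measures) {
          for (d in datasets) {
            s <- compare_enrichments(results[[a]][[ma]][[d]],
                                     results[[b]][[mb]][[d]])$value
            if (s > 0) w <- w + 1L
            else if (s < 0) l <- l + 1L
            else t_ <- t_ + 1L
          }
        }
      }
      W[a, b] <- w; T_[a, b] <- t_; L[a, b] <- l
    }
  }
  list(wins = W, ties = T_, losses = L,
       comparisons_per_cell = comparisons_per_cell(length(measures),
                                                   length(datasets)))
}
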