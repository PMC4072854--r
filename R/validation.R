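# Cluster validity and result-comparison statistics: pair counts and the
# Adjusted Rand Index, the Silhouette width, Fisher-exact (hypergeometric)
# gene-set enrichment with the paired log-ratio comparison score, and the
# Friedman + Nemenyi test battery.

.check_partition_pair <- function(u, v) {
  if (length(u) != length(v)) {
    stop("partitions must cover the same object set", call. = FALSE)
  }
  invisible(NULL)
}

#' Pair-type counts between two partitions
#'
#' Classifies every one of the `n(n-1)/2` object pairs: `a` pairs
#' co-clustered in both partitions, `b` co-clustered in `u` only, `c` in
#' `v` only, `d` separated in both.
#'
#' @param u,v Partition vectors (cluster id per object) over the same
#'   objects.
#' @return Named numeric vector `(a, b, c, d)` summing to `n(n-1)/2`.
#' @export
pair_counts <- function(u, v) {
  .check_partition_pair(u, v)
  tab <- table(u, v)
  n <- length(u)
  tot <- n * (n - 1) / 2
  a <- sum(choose(tab, 2))
  su <- sum(choose(rowSums(tab), 2))
  sv <- sum(choose(colSums(tab), 2))
  c(a = a, b = su - a, c = sv - a, d = tot - su - sv + a)
}

#' Adjusted Rand Index
#'
#' Pair-counting agreement between a partition and a reference, corrected
#' for chance (Hubert-Arabie): `(sum_ij C(n_ij,2) - E) / (M - E)` with
#' `E = sum_i C(a_i,2) * sum_j C(b_j,2) / C(n,2)` and `M` the mean of the
#' two marginal pair sums. 1 for identical partitions (up to relabelling);
#' near 0 for agreement at chance level. When both partitions are trivial
#' (denominator 0): 1 if they are identical, otherwise 0.
#'
#' @param u,v Partition vectors over the same objects.
#' @return ARI value (at most 1).
#' @export
adjusted_rand <- function(u, v) {
  .check_partition_pair(u, v)
  tab <- table(u, v)
  n <- length(u)
  sum_ij <- sum(choose(tab, 2))
  su <- sum(choose(rowSums(tab), 2))
  sv <- sum(choose(colSums(tab), 2))
  expected <- su * sv / choose(n, 2)
  denom <- (su + sv) / 2 - expected
  if (denom == 0) {
    same <- sum_ij == su && sum_ij == sv  # identical up to labels
    return(if (same) 1 else 0)
  }
  (sum_ij - expected) / denom
}

#' Mean Silhouette width of a partition
#'
#' For each object, `u(i)` is the mean distance to its own-cluster
#' co-members and `v(i)` the smallest mean distance to any other cluster;
#' the object's width is `(v(i) - u(i)) / max(v(i), u(i))` and the index is
#' the mean over objects. Singleton clusters score 0 for their object.
#' Defined only for `2 <= k <= n - 1`; outside that range the index is not
#' evaluable and `NA` is returned.
#'
#' @param D Square symmetric distance matrix.
#' @param p Partition vector over the rows of `D`.
#' @return Mean silhouette in `[-1, 1]`, or `NA` when not evaluable.
#' @export
silhouette_width <- function(D, p) {
  Dm <- .check_distmat(D)
  n <- nrow(Dm)
  if (length(p) != n) {
    stop("partition length must match the distance matrix", call. = FALSE)
  }
  ks <- unique(p)
  k <- length(ks)
  if (k < 2 || k > n - 1) return(NA_real_)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(p == p[i])
    if (length(own) == 1) { s[i] <- 0; next }
    u_i <- mean(Dm[i, setdiff(own, i)])
    v_i <- min(vapply(setdiff(ks, p[i]), function(c) {
      mean(Dm[i, p == c])
    }, numeric(1)))
    s[i] <- (v_i - u_i) / max(v_i, u_i)
  }
  mean(s)
}

# ---- enrichment -------------------------------------------------------------

#' Fisher-exact (hypergeometric) gene-set enrichment of a gene partition
#'
#' For every (cluster, gene set) combination, tests whether the overlap
#' between the cluster's genes and the set is larger than expected by
#' chance, with a one-sided hypergeometric tail
#' `P(X >= overlap)`. The background universe is the set of genes present
#' in the dataset (the names of `p`), and gene sets are intersected with it
#' before testing. Entries with `p <= alpha` are retained, sorted by
#' ascending p-value.
#'
#' @param p Named partition vector over genes.
#' @param gene_sets Named list of character vectors (e.g. from [read_gmt]).
#' @param alpha Retention threshold on the raw p-value (default 0.05).
#' @param adjust Optional multiple-testing correction method passed to
#'   [stats::p.adjust]; default `"none"` keeps raw p-values.
#' @return A data frame (`cluster`, `term`, `p`) sorted ascending by `p`;
#'   zero rows when nothing is enriched.
#' @export
fisher_enrichment <- function(p, gene_sets, alpha = 0.05, adjust = "none") {
  genes <- names(p)
  if (is.null(genes)) {
    stop("partition must be named by gene id", call. = FALSE)
  }
  universe <- genes
  sets <- lapply(gene_sets, intersect, universe)
  if (all(lengths(sets) == 0)) {
    warning("no overlap between dataset genes and annotation", call. = FALSE)
    return(data.frame(cluster = integer(0), term = character(0),
                      p = numeric(0)))
  }
  N <- length(universe)
  rows <- list()
  for (cl in sort(unique(p))) {
    cl_genes <- genes[p == cl]
    nc <- length(cl_genes)
    for (term in names(sets)) {
      K <- length(sets[[term]])
      if (K == 0) next
      ov <- length(intersect(cl_genes, sets[[term]]))
      pv <- stats::phyper(ov - 1, K, N - K, nc, lower.tail = FALSE)
      rows[[length(rows) + 1]] <- data.frame(
        cluster = cl, term = term, p = pv, stringsAsFactors = FALSE
      )
    }
  }
  res <- do.call(rbind, rows)
  res$p_adj <- stats::p.adjust(res$p, method = adjust)
  res <- res[res$p_adj <= alpha, c("cluster", "term", "p"), drop = FALSE]
  res <- res[order(res$p), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Signed log-ratio comparison of two enrichment lists
#'
#' Both p-value lists are sorted ascending and compared position-wise over
#' the shorter length; strict wins each way are counted and combined as
#' `log((w1 + 0.5) / (w2 + 0.5))` (the 0.5 pseudocount keeps the ratio
#' defined and the score antisymmetric when a count is zero). Positive
#' values mean the first list has the better (smaller) enrichment p-values.
#'
#' @param r1,r2 Numeric vectors of enrichment p-values, or data frames with
#'   a `p` column as returned by [fisher_enrichment].
#' @return List with `value` (the signed log ratio) and `counts`
#'   (`c(r1_wins, r2_wins)`).
#' @export
compare_enrichments <- function(r1, r2) {
  p1 <- if (is.data.frame(r1)) r1$p else r1
  p2 <- if (is.data.frame(r2)) r2$p else r2
  if (length(p1) == 0 && length(p2) == 0) {
    warning("both enrichment lists are empty; score 0", call. = FALSE)
    return(list(value = 0, counts = c(r1_wins = 0, r2_wins = 0)))
  }
  p1 <- sort(p1)
  p2 <- sort(p2)
  m <- min(length(p1), length(p2))
  w1 <- sum(p1[seq_len(m)] < p2[seq_len(m)])
  w2 <- sum(p2[seq_len(m)] < p1[seq_len(m)])
  list(value = log((w1 + 0.5) / (w2 + 0.5)),
       counts = c(r1_wins = w1, r2_wins = w2))
}

# ---- Friedman / Nemenyi -----------------------------------------------------

#' Friedman rank test over a datasets-by-methods score table
#'
#' Ranks the methods within each dataset (higher score = better = rank 1 is
#' NOT assumed; ranking is ascending, so callers comparing "larger is
#' better" scores should pass `rank_desc = TRUE`), averages ties, and forms
#' the chi-square statistic
#' `12N / (k(k+1)) * sum_j (Rbar_j - (k+1)/2)^2` on `k - 1` degrees of
#' freedom.
#'
#' @param scores Numeric matrix, datasets in rows, methods in columns.
#' @param rank_desc If `TRUE` (default), larger scores get better (smaller)
#'   ranks.
#' @return List with `statistic`, `p_value`, `avg_ranks`, `N`, `k`.
#' @export
friedman_rank_test <- function(scores, rank_desc = TRUE) {
  if (!is.matrix(scores) || nrow(scores) < 2 || ncol(scores) < 2) {
    stop("'scores' must be a matrix with >= 2 datasets and >= 2 methods",
         call. = FALSE)
  }
  N <- nrow(scores)
  k <- ncol(scores)
  r <- t(apply(scores, 1, function(row) {
    rank(if (rank_desc) -row else row, ties.method = "average")
  }))
  avg <- colMeans(r)
  stat <- 12 * N / (k * (k + 1)) * sum((avg - (k + 1) / 2)^2)
  list(statistic = stat,
       p_value = stats::pchisq(stat, df = k - 1, lower.tail = FALSE),
       avg_ranks = avg, N = N, k = k)
}

#' Nemenyi critical difference at alpha = 0.05
#'
#' Two methods differ significantly when their average ranks differ by at
#' least `CD = q_alpha(k) * sqrt(k(k+1) / (6N))`, where `q_alpha(k)` is the
#' Studentized-range quantile at infinite degrees of freedom divided by
#' `sqrt(2)`.
#'
#' @param k Number of methods (`>= 2`).
#' @param N Number of datasets (`>= 1`).
#' @param alpha Significance level (default 0.05).
#' @return The critical difference (positive scalar).
#' @export
nemenyi_cd <- function(k, N, alpha = 0.05) {
  if (k < 2) stop("'k' must be >= 2", call. = FALSE)
  if (N < 1) stop("'N' must be >= 1", call. = FALSE)
  q <- stats::qtukey(1 - alpha, nmeans = k, df = Inf) / sqrt(2)
  q * sqrt(k * (k + 1) / (6 * N))
}
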