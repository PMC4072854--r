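# Clustering on precomputed distance matrices: k-medoids with restarts and
# the three classic agglomerative linkages. Partitions are integer vectors
# (one cluster id in 1..k per object, named by object id).

.check_distmat <- function(D) {
  D <- unclass(D)
  if (!is.matrix(D) || nrow(D) != ncol(D)) {
    stop("'D' must be a square distance matrix", call. = FALSE)
  }
  if (any(!is.finite(D)) || any(D < -1e-12)) {
    stop("'D' must be finite and nonnegative", call. = FALSE)
  }
  if (max(abs(D - t(D))) > 1e-8) {
    stop("'D' must be symmetric", call. = FALSE)
  }
  D
}

# run RNG-dependent code under a seed without disturbing the caller's stream
.with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

.canonical_labels <- function(cl) {
  # relabel clusters 1..k in order of first appearance
  match(cl, unique(cl))
}

# ---- k-medoids --------------------------------------------------------------

#' k-medoids clustering with random restarts
#'
#' The classic medoid-based counterpart of k-means, run directly on a
#' precomputed distance matrix: (i) k distinct objects are drawn at random
#' as medoids, (ii) every object is assigned to its nearest medoid (ties to
#' the smaller medoid index), (iii) each cluster's medoid is replaced by the
#' member minimising the total distance to the other members (ties to the
#' smaller object index). Steps (ii)-(iii) repeat until memberships stop
#' changing or `max_iter` is reached. The whole procedure is restarted
#' `restarts` times (restart `r` seeded with `seed + r`) and the run with
#' the smallest objective -- the total distance of objects to their medoids
#' -- is returned (ties by restart index). If a cluster empties, it is
#' re-seeded with the object farthest from its current medoid.
#'
#' @param D Square symmetric distance matrix (`distmat` or plain matrix).
#' @param k Number of clusters, `1 <= k <= n`.
#' @param restarts Number of random initialisations (default 50).
#' @param seed Base RNG seed; the result is deterministic given it.
#' @param max_iter Iteration cap per restart (default 100).
#' @param trace If `TRUE`, attach the per-iteration objective values of the
#'   winning restart as attribute `objective_trace`.
#' @return Integer partition vector (cluster ids 1..k, named by object id)
#'   with attributes `medoids` (object indices) and `objective`.
#' @export
kmedoids <- function(D, k, restarts = 50, seed = 1, max_iter = 100,
                     trace = FALSE) {
  Dm <- .check_distmat(D)
  n <- nrow(Dm)
  k <- as.integer(k)
  if (k < 1 || k > n) {
    stop("'k' must be between 1 and the number of objects", call. = FALSE)
  }
  best <- NULL
  for (r in seq_len(restarts)) {
    run <- .with_seed(seed + r, .kmedoids_once(Dm, k, max_iter))
    if (is.null(best) || run$objective < best$objective) best <- run
  }
  labels <- .canonical_labels(best$assign)
  names(labels) <- rownames(Dm)
  structure(labels,
            medoids = best$medoids,
            objective = best$objective,
            objective_trace = if (trace) best$trace else NULL,
            k = k)
}

.kmedoids_once <- function(D, k, max_iter) {
  n <- nrow(D)
  medoids <- sort(sample.int(n, k))
  assign_prev <- NULL
  trace <- numeric(0)
  for (iter in seq_len(max_iter)) {
    # nearest medoid; which.min over columns sorted by medoid index breaks
    # ties toward the smaller medoid index
    medoids <- sort(medoids)
    sub <- D[, medoids, drop = FALSE]
    assign <- apply(sub, 1, which.min)
    # re-seed empty clusters with the object farthest from its medoid
    repeat {
      sizes <- tabulate(assign, nbins = k)
      empty <- which(sizes == 0)
      if (length(empty) == 0) break
      cur_d <- D[cbind(seq_len(n), medoids[assign])]
      cand <- setdiff(order(cur_d, decreasing = TRUE), medoids)
      moved <- cand[1]
      medoids[empty[1]] <- moved
      medoids <- sort(medoids)
      sub <- D[, medoids, drop = FALSE]
      assign <- apply(sub, 1, which.min)
    }
    # update medoids: member minimising total within-cluster distance
    for (c in seq_len(k)) {
      members <- which(assign == c)
      if (length(members) == 1) {
        medoids[c] <- members
      } else {
        tot <- colSums(D[members, members, drop = FALSE])
        medoids[c] <- members[which.min(tot)]
      }
    }
    obj <- sum(D[cbind(seq_len(n), medoids[assign])])
    trace <- c(trace, obj)
    if (!is.null(assign_prev) && all(assign == assign_prev)) break
    assign_prev <- assign
  }
  list(assign = assign, medoids = sort(medoids),
       objective = obj, trace = trace)
}

# ---- agglomerative linkage --------------------------------------------------

#' Agglomerative hierarchical clustering on a distance matrix
#'
#' Single-, average- or complete-linkage agglomeration: starting from
#' singleton clusters, the two closest clusters (under the linkage's
#' inter-cluster distance: minimum, mean or maximum cross-pair distance)
#' are merged until one cluster remains.
#'
#' @param D Square symmetric distance matrix.
#' @param method One of `"single"`, `"average"`, `"complete"` (the spec ids
#'   SL / AL / CL also work).
#' @return An [stats::hclust] dendrogram; cut it with [cut_dendrogram].
#' @export
linkage <- function(D, method = c("average", "complete", "single")) {
  aliases <- c(AL = "average", CL = "complete", SL = "single")
  if (length(method) == 1 && method %in% names(aliases)) {
    method <- aliases[[method]]
  }
  method <- match.arg(method)
  Dm <- .check_distmat(D)
  stats::hclust(stats::as.dist(Dm), method = method)
}

#' Cut a dendrogram into exactly k clusters
#'
#' Undoes the last `k - 1` merges of the hierarchy, yielding exactly `k`
#' clusters for any `1 <= k <= n`.
#'
#' @param dendro An [stats::hclust] object from [linkage].
#' @param k Number of clusters.
#' @return Integer partition vector, cluster ids 1..k.
#' @export
cut_dendrogram <- function(dendro, k) {
  stopifnot(inherits(dendro, "hclust"))
  n <- length(dendro$order)
  k <- as.integer(k)
  if (k < 1 || k > n) {
    stop("'k' must be between 1 and the number of leaves", call. = FALSE)
  }
  cl <- stats::cutree(dendro, k = k)
  labels <- .canonical_labels(cl)
  names(labels) <- names(cl)
  labels
}

#' Serialize a dendrogram merge list as TSV (a, b, height)
#'
#' Merge entries use the [stats::hclust] convention: negative values are
#' leaf indices, positive values refer to earlier merges.
#'
#' @param dendro An `hclust` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dendrogram_tsv <- function(dendro, path) {
  stopifnot(inherits(dendro, "hclust"))
  utils::write.table(
    data.frame(a = dendro$merge[, 1], b = dendro$merge[, 2],
               height = .fmt_num(dendro$height)),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = TRUE
  )
  invisible(path)
}

#' Cluster a distance matrix with one of the four methods
#'
#' Dispatcher used by the evaluation scenarios: `"KM"` runs [kmedoids],
#' `"SL"`/`"AL"`/`"CL"` run the corresponding [linkage] and cut at `k`.
#'
#' @param D Distance matrix.
#' @param method `"KM"`, `"SL"`, `"AL"` or `"CL"`.
#' @param k Number of clusters.
#' @param restarts,seed,max_iter Passed to [kmedoids] when `method = "KM"`.
#' @return Integer partition vector.
#' @export
cluster_distmat <- function(D, method = c("AL", "CL", "SL", "KM"), k,
                            restarts = 50, seed = 1, max_iter = 100) {
  method <- match.arg(method)
  if (method == "KM") {
    kmedoids(D, k, restarts = restarts, seed = seed, max_iter = max_iter)
  } else {
    cut_dendrogram(linkage(D, method), k)
  }
}
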