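# Independent oracles used across tests. Each is a deliberately naive
# implementation (double loops, brute enumeration) kept separate from the
# package's code paths.

# O(n^2) pair classification by explicit double loop
oracle_count_pairs <- function(x, y) {
  n <- length(x)
  conc <- disc <- neut <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if ((x[i] < x[j] && y[i] < y[j]) || (x[i] > x[j] && y[i] > y[j])) {
        conc <- conc + 1
      } else if ((x[i] < x[j] && y[i] > y[j]) ||
                 (x[i] > x[j] && y[i] < y[j])) {
        disc <- disc + 1
      } else {
        neut <- neut + 1
      }
    }
  }
  c(concordant = conc, discordant = disc, neutral = neut)
}

# naive jackknife: recompute Pearson on every leave-one-out copy
oracle_jackknife <- function(x, y) {
  vals <- stats::cor(x, y)
  for (i in seq_along(x)) {
    vals <- c(vals, stats::cor(x[-i], y[-i]))
  }
  min(vals)
}

# ARI from the printed pair-count form:
# (a - E) / (M - E), E = (a+b)(a+c)/(a+b+c+d), M = ((a+b)+(a+c))/2
oracle_ari_paircount <- function(u, v) {
  n <- length(u)
  a <- b <- c_ <- d <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      su <- u[i] == u[j]
      sv <- v[i] == v[j]
      if (su && sv) a <- a + 1
      else if (su && !sv) b <- b + 1
      else if (!su && sv) c_ <- c_ + 1
      else d <- d + 1
    }
  }
  tot <- a + b + c_ + d
  e <- (a + b) * (a + c_) / tot
  m <- ((a + b) + (a + c_)) / 2
  if (m == e) return(if (b == 0 && c_ == 0) 1 else 0)
  (a - e) / (m - e)
}

# brute-force per-object silhouette
oracle_silhouette <- function(D, p) {
  n <- nrow(D)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- setdiff(which(p == p[i]), i)
    if (length(own) == 0) { s[i] <- 0; next }
    u <- mean(D[i, own])
    v <- Inf
    for (c in setdiff(unique(p), p[i])) {
      v <- min(v, mean(D[i, which(p == c)]))
    }
    s[i] <- (v - u) / max(v, u)
  }
  mean(s)
}

# single linkage via MST: cut the k-1 largest MST edges (Prim's algorithm)
oracle_single_linkage <- function(D, k) {
  n <- nrow(D)
  in_tree <- c(1L)
  edges <- NULL
  while (length(in_tree) < n) {
    best <- c(Inf, NA, NA)
    for (i in in_tree) {
      for (j in setdiff(seq_len(n), in_tree)) {
        if (D[i, j] < best[1]) best <- c(D[i, j], i, j)
      }
    }
    edges <- rbind(edges, best)
    in_tree <- c(in_tree, best[3])
  }
  keep <- edges[order(edges[, 1])[seq_len(n - k)], , drop = FALSE]
  # connected components over kept edges
  labels <- seq_len(n)
  for (e in seq_len(nrow(keep))) {
    a <- labels[keep[e, 2]]; b <- labels[keep[e, 3]]
    labels[labels == b] <- a
  }
  match(labels, unique(labels))
}

# exact upper-tail spearman p by permutation enumeration (independent of
# the package's memoized implementation)
oracle_spearman_tail <- function(x, y) {
  k <- length(x)
  rx <- rank(x); ry <- rank(y)
  rho_obs <- stats::cor(rx, ry)
  perm_all <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perm_all(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    }
    out
  }
  rhos <- vapply(perm_all(seq_len(k)), function(pr) {
    stats::cor(pr, seq_len(k))
  }, numeric(1))
  mean(rhos >= rho_obs - 1e-12)
}

# random partition with the same cluster sizes as p, labels shuffled
shuffle_partition <- function(p) {
  sample(p)
}

# a random symmetric distance matrix with zero diagonal
random_distmat <- function(n) {
  m <- matrix(stats::runif(n * n), n, n)
  m <- (m + t(m)) / 2
  diag(m) <- 0
  m
}

canon <- function(p) match(p, unique(p))
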