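# Scalar correlation and distance measures: worked examples with
# hand-derived or oracle-derived expected values, plus degenerate-input
# policies.

test_that("rank transform uses average ranks for ties", {
  expect_equal(rank_transform(c(10, 20, 30)), c(1, 2, 3))
  expect_equal(rank_transform(c(5, 5)), c(1.5, 1.5))
  expect_equal(rank_transform(c(3, 1, 4, 1)), c(3, 1.5, 4, 1.5))
  # ranks always sum to n(n+1)/2
  set.seed(42)
  for (i in 1:20) {
    x <- sample(1:5, 8, replace = TRUE)
    expect_equal(sum(rank_transform(x)), 8 * 9 / 2)
  }
  expect_error(rank_transform(c(1, NA)), "non-finite")
})

test_that("pearson matches exact linear relations and the direct formula", {
  expect_equal(pearson_cor(c(1, 2, 3), c(2, 4, 6)), 1)
  expect_equal(pearson_cor(c(1, 2, 3), c(3, 2, 1)), -1)
  x <- c(1, 2, 3, 100); y <- c(3, 1, 2, 100)
  # direct evaluation of the product-moment sums
  num <- sum((x - mean(x)) * (y - mean(y)))
  den <- sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(pearson_cor(x, y), num / den)
  expect_warning(r <- pearson_cor(c(1, 1, 1), c(1, 2, 3)), "degenerate")
  expect_equal(r, 0)
})

test_that("spearman equals pearson on ranks and is monotone-invariant", {
  expect_equal(spearman_cor(c(1, 2, 3), c(1, 8, 27)), 1)
  expect_equal(spearman_cor(c(1, 2, 3), c(3, 2, 1)), -1)
  expect_equal(spearman_cor(c(1, 2, 3), c(1, 3, 2)), 0.5)
  set.seed(7)
  x <- rnorm(15); y <- rnorm(15)
  expect_equal(spearman_cor(x, y),
               pearson_cor(rank_transform(x), rank_transform(y)))
})

test_that("pair counts classify concordant/discordant/neutral exactly", {
  expect_equal(count_pairs(c(1, 2, 3), c(1, 2, 3)),
               c(concordant = 3, discordant = 0, neutral = 0))
  expect_equal(count_pairs(c(1, 2, 3), c(1, 3, 2)),
               c(concordant = 2, discordant = 1, neutral = 0))
  expect_equal(count_pairs(c(1, 1, 2), c(1, 2, 2)),
               c(concordant = 1, discordant = 0, neutral = 2))
})

test_that("goodman-kruskal and kendall tau-a follow their printed forms", {
  expect_equal(goodman_kruskal(c(1, 2, 3), c(3, 2, 1)), -1)
  expect_equal(goodman_kruskal(c(1, 2, 3), c(1, 3, 2)), 1 / 3)
  expect_equal(goodman_kruskal(c(1, 1, 2), c(1, 2, 2)), 1)
  expect_equal(kendall_tau(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(kendall_tau(c(1, 2, 3), c(1, 3, 2)), 1 / 3)
  # neutral pairs depress tau-a below 1 even at perfect agreement
  expect_equal(kendall_tau(c(1, 1, 2), c(1, 2, 2)), 1 / 3)
  expect_lt(kendall_tau(c(1, 1, 2), c(1, 1, 2)), 1)
  expect_warning(g <- goodman_kruskal(c(1, 1), c(2, 2)), "degenerate")
  expect_equal(g, 0)
})

test_that("GK/KE match the O(n^2) enumeration oracle on random pairs", {
  set.seed(101)
  for (i in 1:200) {
    n <- sample(3:50, 1)
    x <- sample(1:10, n, replace = TRUE)   # ties likely
    y <- sample(1:10, n, replace = TRUE)
    p <- oracle_count_pairs(x, y)
    expect_equal(count_pairs(x, y), p)
    if (p[["concordant"]] + p[["discordant"]] > 0) {
      expect_equal(goodman_kruskal(x, y),
                   (p[["concordant"]] - p[["discordant"]]) /
                     (p[["concordant"]] + p[["discordant"]]))
    }
    expect_equal(kendall_tau(x, y),
                 (p[["concordant"]] - p[["discordant"]]) / (n * (n - 1) / 2))
  }
})

test_that("rank-magnitude matches its closed form and is symmetric", {
  expect_equal(rank_magnitude_asym(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(rank_magnitude_asym(c(3, 2, 1), c(1, 2, 3)), -1)
  # hand evaluation: ranks(1,3,2) . (10,20,30) = 130; sorted y (10,20,30);
  # maxrank = 140, minrank = 100 -> (260-140-100)/40 = 0.5
  expect_equal(rank_magnitude_asym(c(1, 3, 2), c(10, 20, 30)), 0.5)
  expect_equal(rank_magnitude(c(1, 3, 2), c(10, 20, 30)),
               (rank_magnitude_asym(c(1, 3, 2), c(10, 20, 30)) +
                  rank_magnitude_asym(c(10, 20, 30), c(1, 3, 2))) / 2)
  set.seed(11)
  for (i in 1:50) {
    x <- rnorm(10); y <- rnorm(10)
    expect_equal(rank_magnitude(x, y), rank_magnitude(y, x))
    expect_gte(rank_magnitude(x, y), -1 - 1e-12)
    expect_lte(rank_magnitude(x, y), 1 + 1e-12)
  }
  expect_warning(r <- rank_magnitude_asym(c(1, 2, 3), c(5, 5, 5)),
                 "degenerate")
  expect_equal(r, 0)
})

test_that("weighted goodman-kruskal follows the fixed piecewise form", {
  expect_equal(weighted_goodman_kruskal(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(weighted_goodman_kruskal(c(1, 2, 3), c(3, 2, 1)), -1)
  # all three pairs concordant: terms min(wx/wy, wy/wx) = 1/2, 1, 1/2
  expect_equal(weighted_goodman_kruskal(c(0, 1, 3), c(0, 2, 3)), 2 / 3)
  # self-correlation is 1 even with ties (double-zero pairs contribute 1)
  expect_equal(weighted_goodman_kruskal(c(1, 1, 2), c(1, 1, 2)), 1)
  set.seed(5)
  for (i in 1:50) {
    x <- rnorm(8); y <- rnorm(8)
    w <- weighted_goodman_kruskal(x, y)
    expect_gte(w, -1 - 1e-12)
    expect_lte(w, 1 + 1e-12)
    expect_equal(weighted_goodman_kruskal(x, x), 1)
  }
})

test_that("minkowski family covers manhattan, euclidean and supremum", {
  expect_equal(minkowski_dist(c(0, 0), c(3, 4), 2), 5)
  expect_equal(minkowski_dist(c(0, 0), c(3, 4), 1), 7)
  expect_equal(minkowski_dist(c(0, 0), c(3, 4), Inf), 4)
  expect_error(minkowski_dist(c(0, 0), c(3, 4), 0.5), "lambda")
  # triangle inequality on random triples
  set.seed(3)
  for (lambda in c(1, 2, Inf)) {
    for (i in 1:30) {
      a <- rnorm(6); b <- rnorm(6); c_ <- rnorm(6)
      expect_lte(minkowski_dist(a, c_, lambda),
                 minkowski_dist(a, b, lambda) +
                   minkowski_dist(b, c_, lambda) + 1e-12)
    }
  }
})

test_that("cosine distance spans [0, 2] with the documented landmarks", {
  expect_equal(cosine_dist(c(1, 2), c(2, 4)), 0)
  expect_equal(cosine_dist(c(1, 0), c(0, 1)), 1)
  expect_equal(cosine_dist(c(1, 0), c(-1, 0)), 2)
  expect_warning(d <- cosine_dist(c(0, 0), c(1, 1)), "degenerate")
  expect_equal(d, 1)
})

test_that("jackknife is the minimum over leave-one-out pearson values", {
  expect_equal(jackknife_cor(c(1, 2, 3, 4), c(2, 4, 6, 8)), 1)
  x <- c(1, 2, 3, 100); y <- c(3, 1, 2, 100)
  expect_equal(jackknife_cor(x, y, incremental = FALSE),
               oracle_jackknife(x, y))
  # outlier removal term is the minimum, far below full-series pearson
  expect_lt(jackknife_cor(x, y), pearson_cor(x, y))
  set.seed(13)
  for (i in 1:200) {
    n <- sample(4:50, 1)
    a <- rnorm(n); b <- rnorm(n)
    jk <- jackknife_cor(a, b, incremental = FALSE)
    expect_equal(jk, oracle_jackknife(a, b), tolerance = 1e-12)
    expect_lte(jk, pearson_cor(a, b) + 1e-12)
    # incremental and naive paths agree
    expect_equal(jackknife_cor(a, b, incremental = TRUE), jk,
                 tolerance = 1e-10)
  }
})

test_that("correlation-to-distance conversion maps [-1,1] to [0,2]", {
  expect_equal(corr_to_dist(1), 0)
  expect_equal(corr_to_dist(-1), 2)
  expect_equal(corr_to_dist(0), 1)
  expect_error(corr_to_dist(1.5), "\\[-1, 1\\]")
})
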