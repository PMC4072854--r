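# Evaluation scenarios: fixed k, best k, silhouette-estimated k, noise
# injection, wins/ties/losses aggregation.

fixture <- gen_sample_dataset(n_objects = 36, n_features = 60, k = 3,
                              separation = 1.5, sd = 0.3, seed = 11)

test_that("fixed-k scenario recovers planted structure at high separation", {
  res <- scenario_fixed_k(fixture, "PE", "AL")
  expect_equal(res$k, 3)
  expect_gte(res$ari, 0.99)
  nolab <- expression_dataset(fixture$mat)
  expect_error(scenario_fixed_k(nolab, "PE", "AL"), "labels")
  # k = 1 reference rejected
  one <- expression_dataset(fixture$mat, labels = rep(1, 36))
  expect_error(scenario_fixed_k(one, "PE", "AL"), "2 classes")
})

test_that("shuffled labels score near zero under fixed-k", {
  set.seed(90)
  shuffled <- expression_dataset(fixture$mat,
                                 labels = sample(fixture$labels))
  res <- scenario_fixed_k(shuffled, "EUC", "AL")
  expect_lt(abs(res$ari), 0.2)
})

test_that("best-k dominates fixed-k and finds the planted k", {
  for (meas in c("PE", "EUC")) {
    for (meth in c("AL", "CL")) {
      fk <- scenario_fixed_k(fixture, meas, meth)
      bk <- scenario_best_k(fixture, meas, meth, k_range = 2:8)
      expect_gte(bk$best_ari, fk$ari)
    }
  }
  bk <- scenario_best_k(fixture, "PE", "AL", k_range = 2:8)
  expect_equal(bk$best_k, 3)
  # degenerate range reduces to fixed-k
  bk3 <- scenario_best_k(fixture, "PE", "AL", k_range = 3)
  fk3 <- scenario_fixed_k(fixture, "PE", "AL")
  expect_equal(bk3$best_ari, fk3$ari)
})

test_that("estimated-k selection is label-blind and finds dominant structure", {
  d4 <- gen_sample_dataset(n_objects = 40, n_features = 60, k = 4,
                           separation = 2, sd = 0.2, seed = 13)
  est <- scenario_estimated_k(d4, "EUC", "AL", k_range = 2:10)
  expect_equal(est$k, 4)
  expect_gte(est$ari, 0.99)
  # identical output with labels withheld
  blind <- expression_dataset(d4$mat)
  est_blind <- scenario_estimated_k(blind, "EUC", "AL", k_range = 2:10)
  expect_equal(est_blind$k, est$k)
  expect_identical(canon(est_blind$partition), canon(est$partition))
  expect_true(is.na(est_blind$ari))
})

test_that("silhouette ties select the smallest k deterministically", {
  # a single compact blob: selection still returns an argmax
  blob <- gen_sample_dataset(n_objects = 15, n_features = 20, k = 1,
                             sd = 0.5, seed = 17)
  est <- scenario_estimated_k(blob, "EUC", "AL", k_range = 2:6)
  est2 <- scenario_estimated_k(blob, "EUC", "AL", k_range = 2:6)
  expect_identical(est$k, est2$k)
  sil <- est$silhouettes
  expect_equal(unname(est$k),
               as.integer(names(sil)[which(sil == max(sil, na.rm = TRUE))[1]]))
})

test_that("noise injection perturbs exactly the requested cells in range", {
  d <- gen_sample_dataset(n_objects = 20, n_features = 50, k = 2, seed = 19)
  expect_identical(inject_noise(d, 0, seed = 1)$mat, d$mat)
  n10 <- inject_noise(d, 10, seed = 1)
  expect_equal(sum(n10$mat != d$mat), 100)  # round(0.10 * 1000)
  n100 <- inject_noise(d, 100, seed = 1)
  expect_true(all(n100$mat >= min(d$mat) & n100$mat <= max(d$mat)))
  expect_identical(inject_noise(d, 10, seed = 1)$mat, n10$mat)
  expect_error(inject_noise(d, 150), "alpha")
})

test_that("noise scenario reproduces clean ARI at alpha 0 and is reproducible", {
  small <- gen_sample_dataset(n_objects = 24, n_features = 40, k = 3,
                              separation = 1.5, sd = 0.3, seed = 23)
  r0 <- scenario_noise(small, "EUC", "AL", alpha_grid = 0, replicates = 5,
                       seed = 1)
  clean <- scenario_fixed_k(small, "EUC", "AL")
  expect_equal(r0$mean_ari, clean$ari)
  expect_equal(r0$sd_ari, 0)
  r1 <- scenario_noise(small, "EUC", "AL", alpha_grid = c(1, 20),
                       replicates = 10, seed = 1)
  r2 <- scenario_noise(small, "EUC", "AL", alpha_grid = c(1, 20),
                       replicates = 10, seed = 1)
  expect_identical(r1, r2)
})

test_that("wins/ties/losses counts are dual and complete", {
  set.seed(91)
  measures <- paste0("m", 1:2)
  datasets <- paste0("d", 1:3)
  make_cell <- function() sort(runif(4, 0, 0.05))
  results <- lapply(setNames(nm = c("A", "B")), function(meth) {
    lapply(setNames(nm = measures), function(m) {
      lapply(setNames(nm = datasets), function(d) make_cell())
    })
  })
  wtl <- wins_ties_losses(results)
  expect_equal(wtl$comparisons_per_cell, 2 * 2 * 3)
  expect_equal(wtl$wins["A", "B"] + wtl$ties["A", "B"] +
                 wtl$losses["A", "B"], 12)
  expect_equal(wtl$wins["A", "B"], wtl$losses["B", "A"])
  expect_equal(wtl$ties["A", "B"], wtl$ties["B", "A"])
  # identical result lists everywhere: all ties
  same <- lapply(setNames(nm = c("A", "B")), function(meth) {
    lapply(setNames(nm = measures), function(m) {
      lapply(setNames(nm = datasets), function(d) c(0.01, 0.02))
    })
  })
  wtl_same <- wins_ties_losses(same)
  expect_equal(wtl_same$ties["A", "B"], 12L)
  # incomplete grids are an error, not silently imputed
  broken <- results
  broken$B$m1$d2 <- NULL
  expect_error(wins_ties_losses(broken), "missing")
})

test_that("benchmark grid marks failing cells instead of imputing them", {
  # time-series measure without timestamps fails for that cell only
  rep <- run_benchmark_grid(fixture, measures = c("EUC", "STS"),
                            methods = "AL", scenario = "fixed_k")
  expect_true(rep$failed[rep$measure == "STS"])
  expect_true(is.na(rep$score[rep$measure == "STS"]))
  expect_false(rep$failed[rep$measure == "EUC"])
  expect_gte(rep$score[rep$measure == "EUC"], 0.9)
})
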