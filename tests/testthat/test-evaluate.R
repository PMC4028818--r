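test_that("adjusted Rand index reproduces hand-computed cases", {
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(1, 1, 2, 2)), 1)
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(2, 2, 1, 1)), 1)
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(1, 2, 1, 2)), -0.5)
  expect_equal(adjusted_rand_index(rep(1, 5), rep(2, 5)), 1)  # degenerate
  expect_error(adjusted_rand_index(c(a = 1, b = 2), c(a = 1, c = 2)),
               "different element sets")
})

test_that("adjusted Rand index agrees with mclust and is relabel-invariant", {
  skip_if_not_installed("mclust")
  withr::with_seed(1, {
    for (i in 1:10) {
      a <- sample(1:4, 30, replace = TRUE)
      b <- sample(1:3, 30, replace = TRUE)
      expect_equal(adjusted_rand_index(a, b),
                   mclust::adjustedRandIndex(a, b), tolerance = 1e-12)
      perm <- sample(4)
      expect_equal(adjusted_rand_index(perm[a], b),
                   adjusted_rand_index(a, b))
    }
  })
})

test_that("ROC AUC equals the Mann-Whitney statistic with tie handling", {
  truth <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  expect_equal(roc_auc(c(5, 4, 3, 2, 1, 0), truth), 1)
  expect_equal(roc_auc(rep(1, 6), truth), 0.5)
  scores <- c(3.2, 1.5, 2.0, 2.0, 0.7, 1.5)
  U <- suppressWarnings(
    stats::wilcox.test(scores[truth], scores[!truth])$statistic)
  expect_equal(roc_auc(scores, truth), unname(U) / 9)
  skip_if_not_installed("pROC")
  expect_equal(roc_auc(scores, truth),
               as.numeric(suppressMessages(pROC::auc(truth, scores))))
  expect_error(roc_auc(1:3, c(TRUE, TRUE, TRUE)), "Both classes")
})

test_that("AUC is invariant under strictly monotone score transforms", {
  withr::with_seed(2, {
    scores <- rnorm(40)
    truth <- rbinom(40, 1, 0.4) == 1
  })
  a <- roc_auc(scores, truth)
  expect_equal(roc_auc(exp(scores), truth), a)
  expect_equal(roc_auc(rank(scores), truth), a)
})

test_that("cluster-module matching picks the majority-overlap cluster", {
  sim <- simulate_regulatory_data(tiny_config(seed = 21))
  labels <- true_partition(sim)        # perfect clustering
  expect_identical(match_clusters_to_modules(labels, sim$truth), 1:2)
})

test_that("the study runner returns a tidy, reproducible report", {
  grid <- data.frame(snr_db = 10, fp_ratio = 0.5, n_samples = 12)
  cfg <- tiny_config()
  st1 <- run_simulation_study(grid, n_reps = 1, seed = 5, config = cfg,
                              n_iter = 60, burn_in = 20)
  st2 <- run_simulation_study(grid, n_reps = 1, seed = 5, config = cfg,
                              n_iter = 60, burn_in = 20)
  expect_identical(as.data.frame(st1), as.data.frame(st2))  # bit-identical
  expect_s3_class(st1, "grn_study")
  expect_true(all(c("ari", "tf_auc", "target_auc") %in% st1$metric))
  expect_true(all(st1$value[st1$metric == "ari"] >= -1 &
                    st1$value[st1$metric == "ari"] <= 1))
  aucs <- st1$value[st1$metric != "ari" & !is.na(st1$value)]
  expect_true(all(aucs >= 0 & aucs <= 1))
  s <- summary(st1)
  expect_true(all(c("min", "median", "max") %in% names(s)))
})

test_that("target identification approaches perfection as noise vanishes", {
  grid <- data.frame(snr_db = 30, fp_ratio = 0, n_samples = 16)
  cfg <- simulation_config(n_foreground = 30, n_background = 30, n_tfs = 20,
                           n_samples = 16, n_modules = 2,
                           tfs_per_module = 4, gene_degree = 3,
                           snr_db = 30, fp_ratio = 0)
  st <- run_simulation_study(grid, n_reps = 1, seed = 8, config = cfg,
                             n_iter = 100, burn_in = 30,
                             metrics = "targets")
  auc <- st$value[st$method == "mAPC-GibbsOS"]
  expect_true(all(auc > 0.95))
})
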