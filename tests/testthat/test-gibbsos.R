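test_that("seed regression matches an independent least-squares oracle", {
  # fixed 6x2 toy, K = 6 samples, M = 2 seed genes
  F <- cbind(c(1, 2, 3, 4, 5, 6), c(2, 1, 4, 3, 6, 5))
  y <- c(1.2, 1.9, 3.4, 3.9, 5.6, 5.9)
  fit <- os_regress(y, F)
  ref <- summary(stats::lm(y ~ F))
  expect_equal(unname(fit$beta), unname(ref$coefficients[, "Estimate"]),
               tolerance = 1e-10)
  expect_equal(unname(fit$t), unname(ref$coefficients[, "t value"]),
               tolerance = 1e-10)
  expect_equal(fit$mse, ref$sigma^2, tolerance = 1e-10)
  expect_equal(fit$dof, 3)   # K - M - 1
})

test_that("perfect fits and orthogonal responses hit their conventions", {
  F <- cbind(c(1, 2, 3, 4, 5, 6), c(-1, 1, -1, 1, -1, 1))
  y_perfect <- 2 + 3 * F[, 1] - F[, 2]
  fit <- os_regress(y_perfect, F)
  expect_equal(fit$mse, 0)
  expect_equal(abs(unname(fit$t)), rep(1e6, 3))  # capped sentinel
  # response orthogonal to the intercept and both columns
  Q <- qr.Q(qr(cbind(1, F)))
  y0 <- rnorm(6)
  y_orth <- y0 - Q %*% crossprod(Q, y0)
  fit0 <- os_regress(drop(y_orth), F)
  expect_equal(unname(fit0$beta), rep(0, 3), tolerance = 1e-10)
  expect_equal(unname(fit0$t), rep(0, 3), tolerance = 1e-8)
  # sample size must exceed parameter count
  expect_error(os_regress(rnorm(3), matrix(rnorm(9), 3, 3)), "samples")
})

test_that("outlier sum follows the two-sided threshold convention", {
  # tau = qt(0.975, 10) = 2.228: 3.0 and -2.8 exceed it, 1.0 does not
  expect_equal(outlier_sum(c(3, 1, -2.8), alpha = 0.05, dof = 10), 5.8)
  expect_equal(outlier_sum(c(0.5, -1, 2), alpha = 0.05, dof = 10), 0)
  tau <- qt(0.975, 10)
  expect_equal(outlier_sum(tau, alpha = 0.05, dof = 10), tau)  # boundary in
  expect_equal(outlier_sum(numeric(0), alpha = 0.05, dof = 10), 0)
  # signed convention drops the negative outlier
  expect_equal(outlier_sum(c(3, 1, -2.8), alpha = 0.05, dof = 10,
                           signed = TRUE), 3)
})

test_that("outlier sum is sign-invariant and monotone in |t|", {
  withr::with_seed(1, t_stats <- rnorm(20, sd = 3))
  os <- outlier_sum(t_stats, alpha = 0.05, dof = 8)
  signs <- sample(c(-1, 1), 20, replace = TRUE)
  expect_equal(outlier_sum(t_stats * signs, alpha = 0.05, dof = 8), os)
  bigger <- t_stats * 1.3
  expect_gte(outlier_sum(bigger, alpha = 0.05, dof = 8), os)
})

test_that("conditional weights normalize, dominate and match the formula", {
  toy <- toy_gibbs_problem()
  seeds <- c(1L, 4L)
  w <- conditional_weights(1, seeds, toy$X, toy$pools)
  expect_equal(sum(w), 1)
  expect_length(w, 3)
  # genes 1 and 2 support each other; the unco-expressed gene 3 gets nothing
  expect_gt(w[["g1"]] + w[["g2"]], 0.95)
  expect_lt(w[["g3"]], 0.05)
  # single-candidate pool gives weight 1
  w1 <- conditional_weights(1, c(1L, 4L), toy$X,
                            list(tfA = 1L, tfB = toy$pools[[2]]))
  expect_equal(unname(w1), 1)
  # direct Eq-by-Eq recomputation through os_regress/outlier_sum
  K <- ncol(toy$X); M <- 2
  os <- sapply(toy$pools[[1]], function(cand) {
    targets <- setdiff(toy$pools[[1]], c(cand, seeds[-1]))
    t_stats <- sapply(targets, function(g) {
      Fm <- t(toy$X[c(cand, seeds[2]), , drop = FALSE])
      os_regress(toy$X[g, ], Fm)$t[[2]]
    })
    outlier_sum(t_stats, alpha = 0.05, dof = K - M - 1)
  })
  expect_equal(unname(w), os / sum(os))
})

test_that("the C++ sampler core reproduces the R conditional weights", {
  sim <- simulate_regulatory_data(tiny_config(seed = 3))
  pools <- candidate_pools(sim$binding,
                           tfs = sim$truth$active_tfs_per_module[[1]])
  # pick pairwise-distinct seeds so the joint design has full rank
  seeds <- integer(length(pools))
  for (j in seq_along(pools))
    seeds[j] <- setdiff(pools[[j]], seeds)[j %% 2 + 1]
  M <- length(pools); K <- ncol(sim$expression)
  for (j in seq_len(M)) {
    for (design in c("joint", "marginal")) {
      dof <- if (design == "joint") K - M - 1 else K - 2
      wr <- conditional_weights(j, seeds, sim$expression, pools,
                                design = design)
      wc <- regmodules:::cw_cpp(t(sim$expression), as.integer(seeds),
                                as.integer(j), lapply(pools, as.integer),
                                design == "joint", qt(0.975, dof), dof,
                                1e6, FALSE)
      expect_equal(unname(wr), as.numeric(wc), tolerance = 1e-12)
    }
  }
})

test_that("gibbs sampling frequencies are proper and reproducible", {
  toy <- toy_gibbs_problem()
  fit <- gibbs_os(toy$X, toy$pools, n_iter = 200, burn_in = 50, seed = 1)
  expect_s3_class(fit, "gibbsos_fit")
  sums <- tapply(fit$frequency$frequency, fit$frequency$tf, sum)
  expect_equal(as.numeric(sums), c(1, 1))
  fit2 <- gibbs_os(toy$X, toy$pools, n_iter = 200, burn_in = 50, seed = 1)
  expect_identical(fit$trace, fit2$trace)
  expect_error(gibbs_os(toy$X, toy$pools, n_iter = 10, burn_in = 10))
})

test_that("a single TF with constant weights samples i.i.d. from them", {
  toy <- toy_gibbs_problem()
  pools <- list(tfA = toy$pools[[1]])
  w <- conditional_weights(1, 1L, toy$X, pools, design = "marginal")
  # weights do not depend on the current seed for a single marginal TF
  expect_equal(w, conditional_weights(1, 2L, toy$X, pools,
                                      design = "marginal"))
  fit <- gibbs_os(toy$X, pools, n_iter = 5000, burn_in = 100,
                  design = "marginal", seed = 2)
  expect_equal(fit$frequency$frequency, unname(w), tolerance = 0.02)
})

test_that("gene scores are counting frequencies with max-over-TF ranking", {
  toy <- toy_gibbs_problem()
  fit <- gibbs_os(toy$X, toy$pools, n_iter = 24, burn_in = 4, seed = 3)
  # recompute frequencies from the raw trace by direct counting
  kept <- fit$trace[, 5:24]
  for (j in 1:2) {
    cnt <- table(factor(kept[j, ], levels = toy$pools[[j]]))
    expect_equal(fit$frequency$frequency[fit$frequency$tf ==
                                           names(toy$pools)[j]],
                 unname(as.numeric(cnt) / 20))
  }
  sc <- score_genes(fit)
  by_gene <- tapply(fit$frequency$frequency, fit$frequency$gene, max)
  expect_equal(sc$score, as.numeric(by_gene[sc$gene]))
  # universe scores report 0 for genes in no pool
  u <- gene_scores(fit, c("g1", "nope"))
  expect_equal(unname(u["nope"]), 0)
})

test_that("noise-free, FP-free simulation separates foreground perfectly", {
  cfg <- tiny_config(snr_db = Inf, fp_ratio = 0, seed = 11, n_samples = 14)
  sim <- simulate_regulatory_data(cfg)
  pools <- candidate_pools(sim$binding,
                           tfs = unlist(sim$truth$active_tfs_per_module))
  fit <- gibbs_os(sim$expression, pools, n_iter = 150, burn_in = 50, seed = 4)
  sc <- gene_scores(fit, rownames(sim$expression))
  expect_equal(roc_auc(sc, sim$truth$foreground_mask), 1)
})

test_that("design selection falls back to marginal when samples are scarce", {
  sim <- simulate_regulatory_data(tiny_config(seed = 12, n_samples = 5))
  pools <- candidate_pools(sim$binding)
  fit <- gibbs_os(sim$expression, pools, n_iter = 30, burn_in = 10, seed = 5)
  expect_identical(fit$design, "marginal")
  expect_error(gibbs_os(sim$expression, pools, n_iter = 30, burn_in = 10,
                        design = "joint"), "marginal")
})
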