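test_that("hypergeometric p-value matches the literal sum on all small cases", {
  for (N in 2:12) for (NB in 0:N) for (Nc in 1:N) {
    for (Nb in 0:min(NB, Nc)) {
      expect_equal(hypergeom_pvalue(N, NB, Nc, Nb),
                   brute_hypergeom(N, NB, Nc, Nb), tolerance = 1e-12)
    }
  }
})

test_that("hypergeometric p-value matches exhaustive cluster enumeration", {
  # all C(10,4) clusters from a population with 5 bound genes
  N <- 10; NB <- 5; Nc <- 4; Nb <- 3
  bound <- seq_len(NB)
  clusters <- utils::combn(N, Nc)
  hits <- colSums(matrix(clusters %in% bound, nrow = Nc))
  expect_equal(mean(hits >= Nb), 55 / 210)
  expect_equal(hypergeom_pvalue(N, NB, Nc, Nb), 55 / 210, tolerance = 1e-12)
  # trivial tails
  expect_equal(hypergeom_pvalue(10, 5, 4, 0), 1)
  expect_equal(hypergeom_pvalue(10, 10, 4, 4), 1)
  expect_error(hypergeom_pvalue(10, 5, 4, 5), "Impossible")
})

test_that("p-values agree with a Monte-Carlo null and are monotone in Nb", {
  N <- 20; NB <- 6; Nc <- 5
  withr::with_seed(1, {
    draws <- replicate(1e5, sum(sample.int(N, Nc) <= NB))
  })
  for (Nb in 1:5) {
    mc <- mean(draws >= Nb)
    p <- hypergeom_pvalue(N, NB, Nc, Nb)
    expect_lt(abs(p - mc), 4 * sqrt(p * (1 - p) / 1e5) + 1e-4)
  }
  p_seq <- sapply(0:5, function(nb) hypergeom_pvalue(N, NB, Nc, nb))
  expect_true(all(diff(p_seq) <= 0))
})

test_that("enrichment scores are capped normal quantiles", {
  expect_equal(pvalue_to_score(0.5), 0)
  expect_equal(pvalue_to_score(0.05), qnorm(0.95), tolerance = 1e-10)
  expect_equal(pvalue_to_score(0.05), 1.6449, tolerance = 1e-4)
  expect_equal(pvalue_to_score(1e-10), 4)   # capped
  expect_equal(pvalue_to_score(0), 4)
  # monotone decreasing
  p <- c(0.9, 0.5, 0.1, 0.01)
  expect_true(all(diff(pvalue_to_score(p)) >= 0))
  expect_error(pvalue_to_score(-0.1))
})

test_that("cluster enrichment produces one sorted row per TF", {
  W <- matrix(0L, 12, 3, dimnames = list(sprintf("g%02d", 1:12),
                                         c("tfA", "tfB", "tfC")))
  W[1:4, "tfA"] <- 1L          # binds exactly the cluster
  W[5:10, "tfB"] <- 1L         # binds none of the cluster
  W[c(1, 2, 11), "tfC"] <- 1L  # partial overlap
  cluster <- sprintf("g%02d", 1:4)
  res <- enrich_cluster(cluster, W, threshold = 0.05)
  expect_identical(nrow(res), 3L)
  expect_true(!is.unsorted(res$p_value))
  rA <- res[res$tf == "tfA", ]
  expect_equal(rA$p_value, 1 / choose(12, 4))  # minimum attainable
  expect_true(rA$enriched)
  rB <- res[res$tf == "tfB", ]
  expect_equal(rB$Nb, 0L)
  expect_equal(rB$p_value, 1)
  expect_false(rB$enriched)
  expect_error(enrich_cluster(character(), W), "empty")
  # per-cluster wrapper covers every (cluster, TF) pair
  labels <- stats::setNames(rep(1:3, each = 4), rownames(W))
  all_res <- enrich_clusters(labels, W)
  expect_identical(nrow(all_res), 9L)
})
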