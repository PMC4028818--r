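test_that("configuration validation rejects impossible setups", {
  expect_s3_class(simulation_config(), "sim_config")
  expect_error(simulation_config(n_foreground = 10, n_modules = 3),
               "equal-sized")
  expect_error(simulation_config(n_foreground = 10, n_background = 7,
                                 n_modules = 2, n_tfs = 16,
                                 tfs_per_module = 3, gene_degree = 2),
               "multiple of the module size")
  expect_error(simulation_config(gene_degree = 9, tfs_per_module = 4),
               "cannot exceed")
  expect_error(simulation_config(n_tfs = 10), "Not enough TFs")
  expect_error(simulation_config(fp_ratio = -1))
})

test_that("binding is modularized with the configured degree", {
  cfg <- tiny_config()
  withr::with_seed(1, b <- generate_binding(cfg))
  W <- b$binding
  expect_identical(dim(W), c(40L, 16L))
  expect_identical(W, b$truth$true_binding)
  # every gene binds exactly gene_degree TFs of its own module's set
  expect_true(all(rowSums(W) == cfg$gene_degree))
  for (m in 1:2) {
    rows <- which(b$truth$module_labels == m)
    tfs <- b$truth$active_tfs_per_module[[m]]
    expect_true(all(W[rows, setdiff(colnames(W), tfs)] == 0))
  }
  # module TF sets are disjoint between modules and from background sets
  all_sets <- c(b$truth$active_tfs_per_module,
                b$truth$background_tfs_per_module)
  expect_identical(anyDuplicated(unlist(all_sets)), 0L)
  # generative partition: 2 foreground modules + 2 background pseudo-modules
  expect_identical(sort(unique(unname(b$truth$partition))), 1:4)
})

test_that("default configuration reproduces the benchmark dimensions", {
  sim <- simulate_regulatory_data(simulation_config(seed = 5))
  expect_identical(dim(sim$expression), c(300L, 20L))
  expect_identical(dim(sim$binding), c(300L, 80L))
  expect_identical(sum(sim$truth$foreground_mask), 100L)
  expect_identical(as.integer(table(sim$truth$module_labels)), c(50L, 50L))
})

test_that("false-positive injection adds the exact count and never deletes", {
  cfg <- tiny_config()
  withr::with_seed(2, b <- generate_binding(cfg))
  tp <- sum(b$binding[b$truth$foreground_mask, ])
  for (fp in c(0, 0.5, 1)) {
    withr::with_seed(3, W2 <- inject_false_positives(b$binding, b$truth, fp))
    expect_true(all(W2 >= b$binding))                      # never deletes
    expect_equal(sum(W2) - sum(b$binding), round(fp * tp))
    # all additions land in foreground rows
    expect_identical(W2[!b$truth$foreground_mask, ],
                     b$binding[!b$truth$foreground_mask, ])
  }
  expect_identical(inject_false_positives(b$binding, b$truth, 0), b$binding)
  expect_error(inject_false_positives(b$binding, b$truth, 100),
               "false positives")
})

test_that("expression follows the log-linear model at the requested SNR", {
  cfg <- tiny_config(snr_db = 5)
  withr::with_seed(4, {
    b <- generate_binding(cfg)
    e <- generate_expression(b$truth, cfg)
  })
  fg <- b$truth$foreground_mask
  signal <- e$truth$regulation_strengths %*% e$truth$tf_activities
  # foreground rows decompose exactly into signal + stored noise
  expect_equal(e$expression[fg, ], (signal + e$truth$noise)[fg, ])
  # empirical SNR of the returned components matches the request
  snr_hat <- 10 * log10(var(as.vector(signal[fg, ])) /
                          var(as.vector(e$truth$noise[fg, ])))
  expect_equal(snr_hat, 5, tolerance = 1e-10)
  # support of A equals the true binding on foreground rows; background rows
  # are outside the factor model and carry no regulation strength
  expect_identical(unname(e$truth$regulation_strengths[fg, ] != 0),
                   unname(b$truth$true_binding[fg, ] == 1))
  expect_true(all(e$truth$regulation_strengths[!fg, ] == 0))
})

test_that("noise-free foreground rows lie in the row space of S", {
  cfg <- tiny_config(snr_db = Inf)
  withr::with_seed(5, {
    b <- generate_binding(cfg)
    e <- generate_expression(b$truth, cfg)
  })
  # project each foreground row onto the row space of S (rank <= K)
  Q <- qr.Q(qr(t(e$truth$tf_activities)))
  fg_rows <- e$expression[b$truth$foreground_mask, ]
  resid <- fg_rows - fg_rows %*% Q %*% t(Q)
  expect_lt(max(abs(resid)), 1e-8)
})

test_that("background row variance matches foreground as samples grow", {
  cfg <- tiny_config(n_samples = 1000, snr_db = 5)
  sim <- simulate_regulatory_data(cfg)
  fg <- sim$truth$foreground_mask
  ratio <- var(as.vector(sim$expression[!fg, ])) /
    var(as.vector(sim$expression[fg, ]))
  expect_equal(ratio, 1, tolerance = 0.05)
})

test_that("simulation is bit-reproducible under a fixed seed", {
  a <- simulate_regulatory_data(tiny_config(seed = 99))
  b <- simulate_regulatory_data(tiny_config(seed = 99))
  expect_identical(a$expression, b$expression)
  expect_identical(a$binding, b$binding)
  expect_identical(a$truth$regulation_strengths, b$truth$regulation_strengths)
  c <- simulate_regulatory_data(tiny_config(seed = 100))
  expect_false(identical(a$expression, c$expression))
})
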