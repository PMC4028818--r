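#' Configuration for the regulatory-network simulator
#'
#' Bundles every parameter of the synthetic benchmark: a set of foreground
#' genes organised into co-regulated modules, each driven by a disjoint set of
#' transcription factors (TFs), plus background genes whose expression is pure
#' noise but whose motif-binding rows carry their own modularized structure.
#' Expression follows the log-linear model `X = A %*% S + noise` on the
#' foreground block, where `A` holds regulation strengths on the support of the
#' true binding matrix and `S` holds standard-Gaussian TF activities.
#'
#' The defaults reproduce the benchmark conditions used throughout the package:
#' 300 genes (100 foreground in 2 modules of 50, 200 background), 80 TFs,
#' 20 samples, SNR 5 dB and a false-positive ratio of 1.
#'
#' @param n_foreground Number of truly regulated (foreground) genes. Must be a
#'   multiple of `n_modules`.
#' @param n_background Number of unregulated (background) genes; may be 0.
#'   Background genes are organised into pseudo-modules of the same size as the
#'   foreground modules, so `n_background` must be a multiple of
#'   `n_foreground / n_modules` when positive.
#' @param n_tfs Total number of TFs (columns of the binding matrix).
#' @param n_samples Number of samples (columns of the expression matrix).
#' @param n_modules Number of co-regulated foreground modules.
#' @param snr_db Signal-to-noise ratio in dB applied globally to the foreground
#'   expression block: `10*log10(var(signal)/var(noise))`. Use `Inf` for
#'   noise-free data.
#' @param fp_ratio Number of injected false-positive binding connections over
#'   the number of true-positive connections within foreground rows.
#' @param tfs_per_module Number of TFs actively regulating each foreground
#'   module. TF sets are disjoint across modules; TFs left over are assigned to
#'   the background pseudo-modules.
#' @param gene_degree Number of its module's TFs that each gene binds.
#' @param strength_dist Distribution of the nonzero regulation strengths in
#'   `A`: `"uniform"` (U(0.5, 1.5), the default: positive activation
#'   strengths of comparable size, which gives genes of a module the strong
#'   positive co-expression that co-regulation implies), `"halfnormal"`
#'   (|N(0,1)|, positive but dispersed, weaker co-expression) or `"gaussian"`
#'   (signed N(0,1): within-module expression correlation is then ~0 and
#'   expression-based clustering cannot see the modules).
#' @param seed Optional integer seed; when set, [simulate_regulatory_data()]
#'   is bit-reproducible.
#'
#' @return An object of class `sim_config` (a validated list).
#' @seealso [simulate_regulatory_data()]
#' @export
#' @examples
#' simulation_config(n_foreground = 10, n_background = 10, n_tfs = 12,
#'                   n_samples = 8, n_modules = 2, tfs_per_module = 3,
#'                   gene_degree = 2)
simulation_config <- function(n_foreground = 100, n_background = 200,
                              n_tfs = 80, n_samples = 20, n_modules = 2,
                              snr_db = 5, fp_ratio = 1,
                              tfs_per_module = 3, gene_degree = 3,
                              strength_dist = c("uniform", "halfnormal",
                                                "gaussian"),
                              seed = NULL) {
  strength_dist <- match.arg(strength_dist)
  stopifnot(n_foreground >= 1, n_background >= 0, n_tfs >= 1, n_samples >= 1,
            n_modules >= 1, fp_ratio >= 0, tfs_per_module >= 1,
            gene_degree >= 1)
  if (n_modules > n_foreground)
    stop("`n_modules` cannot exceed `n_foreground`.")
  if (n_foreground %% n_modules != 0)
    stop("`n_foreground` must split into `n_modules` equal-sized modules.")
  module_size <- n_foreground / n_modules
  if (gene_degree > tfs_per_module)
    stop("`gene_degree` cannot exceed `tfs_per_module`.")
  if (n_modules * tfs_per_module > n_tfs)
    stop("`n_tfs` is too small for ", n_modules, " modules of ",
         tfs_per_module, " TFs each.")
  bg_modules <- 0L
  if (n_background > 0) {
    if (n_background %% module_size != 0)
      stop("`n_background` must be a multiple of the module size (",
           module_size, ") so background pseudo-modules mirror the ",
           "foreground modules.")
    bg_modules <- as.integer(n_background / module_size)
    if ((n_modules + bg_modules) * tfs_per_module > n_tfs)
      stop("Not enough TFs: the ", n_modules, " foreground modules and ",
           bg_modules, " background pseudo-modules need ",
           (n_modules + bg_modules) * tfs_per_module, " disjoint TFs, but ",
           "`n_tfs` is ", n_tfs, ".")
  }
  structure(list(
    n_foreground = as.integer(n_foreground),
    n_background = as.integer(n_background),
    n_tfs = as.integer(n_tfs), n_samples = as.integer(n_samples),
    n_modules = as.integer(n_modules), snr_db = snr_db, fp_ratio = fp_ratio,
    tfs_per_module = as.integer(tfs_per_module),
    gene_degree = as.integer(gene_degree),
    strength_dist = strength_dist,
    module_size = as.integer(module_size), bg_modules = bg_modules,
    seed = if (is.null(seed)) NULL else as.integer(seed)
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Simulation configuration\n")
  cat(sprintf("  genes:   %d foreground (%d modules of %d) + %d background\n",
              x$n_foreground, x$n_modules, x$module_size, x$n_background))
  cat(sprintf("  TFs:     %d (%d active per module), degree %d\n",
              x$n_tfs, x$tfs_per_module, x$gene_degree))
  cat(sprintf("  samples: %d   SNR: %s dB   FP ratio: %g\n",
              x$n_samples, format(x$snr_db), x$fp_ratio))
  invisible(x)
}

gene_ids <- function(config) {
  n <- config$n_foreground + config$n_background
  sprintf("g%03d", seq_len(n))
}

tf_ids <- function(config) sprintf("tf%02d", seq_len(config$n_tfs))

#' Generate a modularized motif-binding matrix with ground truth
#'
#' Partitions the foreground genes into equal-sized modules with disjoint
#' active-TF sets and gives each gene `gene_degree` bindings drawn uniformly
#' from its module's TFs. Background genes receive the same modularized scheme
#' on the remaining TFs (disjoint pseudo-modules), so that the binding matrix
#' carries structure everywhere but foreground and background structure never
#' overlap. The result is the pre-false-positive truth: `binding` equals
#' `truth$true_binding`.
#'
#' @param config A [simulation_config()] object. Uses the caller's RNG stream.
#' @return A list with `binding` (binary genes x TFs matrix) and `truth`, a
#'   list holding `true_binding`, `foreground_mask`, `module_labels` (NA for
#'   background genes), `partition` (full generative partition: foreground
#'   modules then background pseudo-modules), and `active_tfs_per_module`.
#' @export
generate_binding <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_foreground + config$n_background
  genes <- gene_ids(config)
  tfs <- tf_ids(config)
  W <- matrix(0L, n, config$n_tfs, dimnames = list(genes, tfs))

  fg_tf_sets <- split(seq_len(config$n_modules * config$tfs_per_module),
                      rep(seq_len(config$n_modules),
                          each = config$tfs_per_module))
  module_labels <- rep(NA_integer_, n)
  module_labels[seq_len(config$n_foreground)] <-
    rep(seq_len(config$n_modules), each = config$module_size)

  for (i in seq_len(config$n_foreground)) {
    pool <- fg_tf_sets[[module_labels[i]]]
    W[i, sample(pool, config$gene_degree)] <- 1L
  }

  bg_tf_sets <- list()
  partition <- module_labels
  if (config$n_background > 0) {
    # mirror the foreground scheme: each pseudo-module gets its own disjoint
    # block of tfs_per_module TFs; TFs beyond the blocks stay inactive
    left <- setdiff(seq_len(config$n_tfs), unlist(fg_tf_sets))
    used <- left[seq_len(config$bg_modules * config$tfs_per_module)]
    bg_tf_sets <- split(used, rep(seq_len(config$bg_modules),
                                  each = config$tfs_per_module))
    bg_idx <- config$n_foreground + seq_len(config$n_background)
    bg_mod <- rep(seq_len(config$bg_modules), each = config$module_size)
    partition[bg_idx] <- config$n_modules + bg_mod
    for (k in seq_along(bg_idx)) {
      pool <- bg_tf_sets[[bg_mod[k]]]
      W[bg_idx[k], sample(pool, config$gene_degree)] <- 1L
    }
  }

  truth <- list(
    true_binding = W,
    foreground_mask = stats::setNames(seq_len(n) <= config$n_foreground, genes),
    module_labels = stats::setNames(module_labels, genes),
    partition = stats::setNames(partition, genes),
    active_tfs_per_module = lapply(fg_tf_sets, function(i) tfs[i]),
    background_tfs_per_module = lapply(bg_tf_sets, function(i) tfs[i])
  )
  list(binding = W, truth = truth)
}

#' Inject false-positive binding connections into foreground rows
#'
#' Adds `round(fp_ratio * TP)` spurious 1-entries uniformly at random among the
#' zero cells of the foreground rows, where `TP` is the number of true-positive
#' entries in those rows. Existing connections are never removed, so the input
#' is element-wise less than or equal to the output.
#'
#' @param W Binary binding matrix (typically `truth$true_binding`).
#' @param truth Truth list from [generate_binding()] (supplies the foreground
#'   mask).
#' @param fp_ratio Nonnegative false-positive to true-positive ratio.
#' @return The contaminated binding matrix.
#' @export
inject_false_positives <- function(W, truth, fp_ratio) {
  stopifnot(all(W %in% c(0L, 1L)), fp_ratio >= 0)
  fg <- truth$foreground_mask
  tp <- sum(W[fg, , drop = FALSE])
  n_fp <- round(fp_ratio * tp)
  if (n_fp == 0) return(W)
  zero_cells <- which(W == 0 & matrix(fg, nrow(W), ncol(W)))
  if (length(zero_cells) < n_fp)
    stop("Cannot place ", n_fp, " false positives: only ", length(zero_cells),
         " empty foreground cells are available.")
  W[sample(zero_cells, n_fp)] <- 1L
  W
}

#' Generate expression data under the log-linear model
#'
#' Foreground rows are `A %*% S + noise` with `A` supported on the true binding
#' matrix and `S` i.i.d. standard Gaussian TF activities; the noise is i.i.d.
#' Gaussian rescaled so that the empirical SNR of the foreground block equals
#' `snr_db` exactly. Background rows are standard-Gaussian samples rescaled so
#' that their empirical variance matches the foreground block's. All values are
#' treated as log-scale expression; no exponentiation is performed anywhere
#' downstream.
#'
#' @param truth Truth list from [generate_binding()].
#' @param config The matching [simulation_config()].
#' @return A list with `expression` (genes x samples matrix) and `truth`
#'   augmented with `regulation_strengths` (A), `tf_activities` (S) and
#'   `noise` (background rows zero; their expression is itself noise).
#' @export
generate_expression <- function(truth, config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_foreground + config$n_background
  K <- config$n_samples
  genes <- rownames(truth$true_binding)
  samples <- sprintf("s%02d", seq_len(K))

  S <- matrix(rnorm(config$n_tfs * K), config$n_tfs, K,
              dimnames = list(colnames(truth$true_binding), samples))
  A <- matrix(0, n, config$n_tfs,
              dimnames = dimnames(truth$true_binding))
  fg <- which(truth$foreground_mask)
  nz <- which(truth$true_binding[fg, , drop = FALSE] == 1)
  vals <- switch(config$strength_dist,
                 uniform = stats::runif(length(nz), 0.5, 1.5),
                 halfnormal = abs(rnorm(length(nz))),
                 gaussian = rnorm(length(nz)))
  A_fg <- A[fg, , drop = FALSE]
  A_fg[nz] <- vals
  A[fg, ] <- A_fg

  signal <- A %*% S
  v_sig <- var(as.vector(signal[fg, , drop = FALSE]))
  if (!is.finite(config$snr_db) && config$snr_db > 0) {
    noise <- matrix(0, n, K, dimnames = list(genes, samples))
  } else {
    if (v_sig <= 0)
      stop("Foreground signal has zero variance; SNR is undefined.")
    target_var <- v_sig / 10^(config$snr_db / 10)
    raw <- matrix(rnorm(length(fg) * K), length(fg), K)
    raw <- raw / sd(as.vector(raw)) * sqrt(target_var)
    noise <- matrix(0, n, K, dimnames = list(genes, samples))
    noise[fg, ] <- raw
  }

  X <- signal + noise
  if (config$n_background > 0) {
    bg <- which(!truth$foreground_mask)
    v_fg <- var(as.vector(X[fg, , drop = FALSE]))
    raw <- matrix(rnorm(length(bg) * K), length(bg), K)
    X[bg, ] <- raw / sd(as.vector(raw)) * sqrt(v_fg)
  }
  dimnames(X) <- list(genes, samples)

  truth$regulation_strengths <- A
  truth$tf_activities <- S
  truth$noise <- noise
  list(expression = X, truth = truth)
}

#' Simulate a full synthetic regulatory-network benchmark dataset
#'
#' Runs [generate_binding()], [inject_false_positives()] and
#' [generate_expression()] under one seed and returns everything needed to
#' benchmark module discovery and target-gene identification with full ground
#' truth.
#'
#' @param config A [simulation_config()]. If `config$seed` is set the result is
#'   bit-reproducible.
#' @return An object of class `grn_sim`: a list with `expression`, `binding`
#'   (contaminated), `truth` and `config`.
#' @export
#' @examples
#' sim <- simulate_regulatory_data(simulation_config(
#'   n_foreground = 20, n_background = 20, n_tfs = 16, n_samples = 10,
#'   n_modules = 2, tfs_per_module = 4, gene_degree = 2, seed = 1))
#' dim(sim$expression)
simulate_regulatory_data <- function(config = simulation_config()) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) withr::local_seed(config$seed)
  b <- generate_binding(config)
  W <- inject_false_positives(b$binding, b$truth, config$fp_ratio)
  e <- generate_expression(b$truth, config)
  structure(list(expression = e$expression, binding = W, truth = e$truth,
                 config = config),
            class = "grn_sim")
}

#' @export
print.grn_sim <- function(x, ...) {
  cat("Simulated regulatory-network dataset\n")
  print(x$config)
  cat(sprintf("  binding: %d true + %d injected false-positive connections\n",
              sum(x$truth$true_binding), sum(x$binding) -
                sum(x$truth$true_binding)))
  invisible(x)
}

#' Ground-truth generative partition of a simulated dataset
#'
#' @param sim A `grn_sim` object.
#' @return Named integer vector: foreground module ids followed by background
#'   pseudo-module ids.
#' @export
true_partition <- function(sim) {
  stopifnot(inherits(sim, "grn_sim"))
  sim$truth$partition
}
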