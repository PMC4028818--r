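#' Per-TF candidate gene pools
#'
#' For each TF, the candidate targets are the genes (optionally restricted to
#' a cluster) with a candidate binding `w(i,j) = 1`. TFs with an empty pool
#' are dropped with a message, since the sampler requires one seed per TF.
#'
#' @param W Binary genes x TFs binding matrix.
#' @param genes Optional subset of genes (ids or indices) to restrict pools
#'   to, e.g. the members of one cluster.
#' @param tfs Optional subset of TFs (ids or indices) to build pools for,
#'   e.g. the TFs enriched in the cluster.
#' @return Named list (one element per retained TF) of integer row indices
#'   into `W`/`X`, with attribute `genes` = rownames(W).
#' @export
candidate_pools <- function(W, genes = NULL, tfs = NULL) {
  W <- as.matrix(W)
  gset <- seq_len(nrow(W))
  if (!is.null(genes)) {
    gset <- if (is.numeric(genes)) as.integer(genes)
            else match(genes, rownames(W))
    if (anyNA(gset)) stop("Unknown gene ids in `genes`.")
  }
  tset <- seq_len(ncol(W))
  if (!is.null(tfs)) {
    tset <- if (is.numeric(tfs)) as.integer(tfs) else match(tfs, colnames(W))
    if (anyNA(tset)) stop("Unknown TF ids in `tfs`.")
  }
  pools <- lapply(tset, function(j) gset[W[gset, j] == 1])
  names(pools) <- colnames(W)[tset] %||% as.character(tset)
  keep <- lengths(pools) > 0
  if (any(!keep))
    message("Dropping ", sum(!keep), " TF(s) with no candidate gene.")
  structure(pools[keep], genes = rownames(W))
}

#' Least-squares regression of a gene on a seed-gene design
#'
#' Fits `y ~ F` by ordinary least squares (with an intercept by default) and
#' returns the coefficient estimates, the mean squared error with
#' `dof = K - M - 1` degrees of freedom, and the per-coefficient t statistics
#' `t_m = beta_m / sqrt(MSE * C_mm)` where `C = (F'F)^{-1}`.
#'
#' A singular `F'F` (e.g. duplicated seed genes) is handled by the
#' Moore-Penrose pseudo-inverse and flagged. A perfect fit (`MSE = 0`) would
#' make every t infinite; the statistics are instead reported at the sentinel
#' `cap` (sign-preserving) so downstream outlier sums stay finite.
#'
#' @param y Numeric response of length K (one gene's expression over samples).
#' @param F K x M design matrix of seed-gene expression (no intercept column).
#' @param include_intercept Prepend an intercept column (default TRUE).
#' @param cap Sentinel magnitude for t statistics of perfect fits.
#' @return List with `beta`, `mse`, `t` (length M+1 including the intercept
#'   when fitted), `dof` and `rank_deficient`.
#' @export
os_regress <- function(y, F, include_intercept = TRUE, cap = 1e6) {
  F <- as.matrix(F)
  K <- length(y)
  stopifnot(nrow(F) == K)
  Fd <- if (include_intercept) cbind(`(Intercept)` = 1, F) else F
  P <- ncol(Fd)
  dof <- K - P
  if (dof < 1)
    stop("Need more samples than fitted parameters: K = ", K,
         " but the design has ", P, " columns.")
  G <- crossprod(Fd)
  # symmetric eigenvalue pseudo-inverse: exact inverse for full-rank designs,
  # Moore-Penrose otherwise (duplicated seed genes); same rule as the C++ core
  e <- eigen(G, symmetric = TRUE)
  keep <- e$values > 1e-10 * max(abs(e$values), 1e-300)
  rank_deficient <- !all(keep)
  V <- e$vectors[, keep, drop = FALSE]
  C <- V %*% (t(V) / e$values[keep])
  beta <- drop(C %*% crossprod(Fd, y))
  fitted_ss <- drop(crossprod(crossprod(Fd, y), beta))
  rss <- max(sum(y^2) - fitted_ss, 0)
  perfect <- rss <= 1e-9 * (sum(y^2) + 1e-300)
  mse <- rss / dof
  se2 <- mse * diag(C)
  t <- ifelse(perfect | se2 <= 0,
              ifelse(beta >= 0, cap, -cap),
              beta / sqrt(pmax(se2, .Machine$double.xmin)))
  t <- pmin(pmax(t, -cap), cap)
  names(t) <- names(beta) <- colnames(Fd)
  list(beta = beta, mse = mse, t = t, dof = dof,
       rank_deficient = rank_deficient)
}

#' Outlier-sum statistic of regression t statistics
#'
#' Sums the t statistics that exceed the Student-t threshold
#' `tau = qt(1 - alpha/2, dof)`. The default two-sided convention sums `|t|`
#' over `|t| >= tau` (a strong negative association supports the seed choice
#' as much as a strong positive one); `signed = TRUE` gives the literal
#' one-sided reading `sum t * 1{t >= tau}`. The boundary is included.
#'
#' @param t_stats Numeric vector of t statistics (may be empty).
#' @param alpha Significance level in `(0, 1)`; the threshold is the upper
#'   `alpha/2` quantile.
#' @param dof Degrees of freedom (>= 1).
#' @param signed Use the one-sided signed convention.
#' @return Nonnegative scalar outlier sum.
#' @export
#' @examples
#' outlier_sum(c(3, 1, -2.8), alpha = 0.05, dof = 10) # 5.8
outlier_sum <- function(t_stats, alpha = 0.05, dof, signed = FALSE) {
  stopifnot(alpha > 0, alpha < 1, dof >= 1)
  if (length(t_stats) == 0) return(0)
  tau <- qt(1 - alpha / 2, dof)
  if (signed) sum(t_stats[t_stats >= tau])
  else sum(abs(t_stats)[abs(t_stats) >= tau])
}

#' Conditional seed-sampling weights for one TF
#'
#' For each candidate seed `theta_ji` of TF `j`, the outlier sum is computed
#' by fixing `theta_j = theta_ji` in the current seed state, regressing every
#' other candidate gene of TF `j` on the seed design, and summing the
#' threshold-exceeding t statistics of the TF-`j` coefficient. The weights are
#' the outlier sums normalized to total 1 (uniform if all are zero, which
#' keeps the chain irreducible). Candidates currently serving as another TF's
#' seed are excluded from the regressed targets of the joint design: a design
#' column regressed on itself fits perfectly and would saturate every outlier
#' sum at the cap.
#'
#' With `design = "joint"` the design holds all current seeds (plus
#' intercept); with `"marginal"` it holds only TF `j`'s candidate seed, the
#' fallback used when the sample size cannot support the joint design.
#'
#' @param j Index of the TF within `pools`.
#' @param seeds Integer vector of current seed gene rows, one per TF
#'   (`seeds[m]` must lie in `pools[[m]]`).
#' @param X Expression matrix (genes x samples).
#' @param pools Candidate pools from [candidate_pools()].
#' @param alpha Outlier-sum significance level.
#' @param design `"joint"` or `"marginal"`.
#' @param cap Sentinel for perfect-fit t statistics.
#' @param signed Signed outlier-sum convention (see [outlier_sum()]).
#' @return Named numeric weights over `pools[[j]]`, summing to 1.
#' @export
conditional_weights <- function(j, seeds, X, pools, alpha = 0.05,
                                design = c("joint", "marginal"), cap = 1e6,
                                signed = FALSE) {
  design <- match.arg(design)
  X <- as.matrix(X)
  M <- length(pools)
  stopifnot(length(seeds) == M, j >= 1, j <= M)
  pool <- pools[[j]]
  K <- ncol(X)
  dof <- if (design == "joint") K - M - 1 else K - 2
  if (dof < 1)
    stop("Design not estimable: ", K, " samples cannot support ",
         if (design == "joint") M else 1, " seed column(s) plus intercept.")
  os <- vapply(pool, function(cand) {
    excl <- if (design == "joint") c(cand, seeds[-j]) else cand
    targets <- setdiff(pool, excl)
    if (length(targets) == 0) return(0)
    Fm <- if (design == "joint") {
      th <- seeds; th[j] <- cand
      t(X[th, , drop = FALSE])
    } else {
      t(X[cand, , drop = FALSE])
    }
    jidx <- if (design == "joint") j + 1L else 2L
    t_stats <- vapply(targets, function(g) {
      os_regress(X[g, ], Fm, cap = cap)$t[[jidx]]
    }, numeric(1))
    outlier_sum(t_stats, alpha = alpha, dof = dof, signed = signed)
  }, numeric(1))
  w <- if (sum(os) <= 0) rep(1 / length(pool), length(pool)) else os / sum(os)
  stats::setNames(w, rownames(X)[pool] %||% as.character(pool))
}

#' Gibbs sampler over seed genes with outlier-sum conditionals (GibbsOS)
#'
#' Identifies true target (foreground) genes among the candidates of a set of
#' TFs. One seed gene per TF is held; each sweep visits the TFs in fixed
#' order and resamples TF `j`'s seed from the conditional weights of
#' [conditional_weights()]. After burn-in, the marginal sampling frequency of
#' each candidate approximates its posterior probability of being a true
#' target: genes sampled often are likely foreground.
#'
#' The joint seed design needs `K > M + 1` samples for `M` TFs; with
#' `design = "auto"` (default) the sampler uses the joint design when
#' estimable and otherwise falls back to per-TF marginal regression
#' (`dof = K - 2`), which keeps the method defined for large TF panels or
#' small sample sizes at the cost of ignoring cross-TF adjustment.
#'
#' The numerical core runs in C++; an equivalent pure-R path exists through
#' [conditional_weights()] and is used to validate the core.
#'
#' @inheritParams conditional_weights
#' @param n_iter Total sweeps.
#' @param burn_in Initial sweeps discarded before computing frequencies
#'   (`n_iter > burn_in`).
#' @param design `"auto"`, `"joint"` or `"marginal"`.
#' @param seed Optional integer seed for reproducibility.
#' @return An object of class `gibbsos_fit`: `trace` (TFs x n_iter matrix of
#'   sampled gene rows), `frequency` tibble (`tf, gene, frequency`; per TF the
#'   frequencies sum to 1), `pools`, `design`, `burn_in`, `alpha`, plus the
#'   gene universe.
#' @export
#' @examples
#' sim <- simulate_regulatory_data(simulation_config(
#'   n_foreground = 20, n_background = 20, n_tfs = 16, n_samples = 30,
#'   n_modules = 2, tfs_per_module = 4, gene_degree = 2, fp_ratio = 0.5,
#'   seed = 1))
#' pools <- candidate_pools(sim$binding, tfs = sim$truth$active_tfs_per_module[[1]])
#' fit <- gibbs_os(sim$expression, pools, n_iter = 50, burn_in = 10, seed = 1)
#' head(score_genes(fit))
gibbs_os <- function(X, pools, n_iter = 500, burn_in = 100, alpha = 0.05,
                     design = c("auto", "joint", "marginal"), cap = 1e6,
                     signed = FALSE, seed = NULL) {
  design <- match.arg(design)
  X <- as.matrix(X)
  stopifnot(n_iter > burn_in, burn_in >= 0, length(pools) >= 1,
            all(lengths(pools) > 0))
  M <- length(pools)
  K <- ncol(X)
  if (design == "auto")
    design <- if (K > M + 1) "joint" else "marginal"
  joint <- design == "joint"
  dof <- if (joint) K - M - 1 else K - 2
  if (dof < 1)
    stop("Design not estimable with ", K, " samples and ", M, " TFs; use ",
         "design = \"marginal\" (needs K >= 3).")
  tau <- qt(1 - alpha / 2, dof)
  if (!is.null(seed)) withr::local_seed(seed)
  trace <- gibbs_cpp(t(X), lapply(pools, as.integer), as.integer(n_iter),
                     joint, tau, dof, cap, signed)
  rownames(trace) <- names(pools)
  kept <- trace[, (burn_in + 1):n_iter, drop = FALSE]
  freq <- purrr::map_dfr(seq_len(M), function(j) {
    cnt <- tabulate(match(kept[j, ], pools[[j]]), nbins = length(pools[[j]]))
    tibble::tibble(tf = names(pools)[j],
                   gene = rownames(X)[pools[[j]]] %||%
                     as.character(pools[[j]]),
                   frequency = cnt / ncol(kept))
  })
  structure(list(trace = trace, frequency = freq, pools = pools,
                 design = design, burn_in = burn_in, n_iter = n_iter,
                 alpha = alpha, genes = rownames(X)),
            class = "gibbsos_fit")
}

#' @export
print.gibbsos_fit <- function(x, ...) {
  cat(sprintf("GibbsOS fit: %d TFs, %d sweeps (%d burn-in), %s design\n",
              nrow(x$trace), x$n_iter, x$burn_in, x$design))
  top <- dplyr::slice_max(dplyr::group_by(x$frequency, .data$tf),
                          .data$frequency, n = 1, with_ties = FALSE)
  cat("  top seed per TF (first 5):\n")
  print(utils::head(as.data.frame(top), 5))
  invisible(x)
}

#' Per-gene sampling-frequency scores from a GibbsOS fit
#'
#' The per-(TF, gene) score is the post-burn-in marginal sampling frequency;
#' a gene's overall score for ranking is its maximum frequency over TFs.
#'
#' @param fit A `gibbsos_fit`.
#' @return Tibble `gene, score` sorted decreasing; genes in no pool are absent
#'   (see [gene_scores()] for the full universe).
#' @export
score_genes <- function(fit) {
  stopifnot(inherits(fit, "gibbsos_fit"))
  out <- dplyr::summarise(dplyr::group_by(fit$frequency, .data$gene),
                          score = max(.data$frequency), .groups = "drop")
  dplyr::arrange(out, dplyr::desc(.data$score), .data$gene)
}

#' Scores over a full gene universe
#'
#' Like [score_genes()] but reporting 0 for genes that were candidates of no
#' TF, so that rankings can be evaluated over a whole cluster or gene pool.
#'
#' @param fit A `gibbsos_fit`.
#' @param genes Character vector of gene ids defining the universe (default:
#'   all genes of the expression matrix the fit was computed from).
#' @return Named numeric vector of scores over `genes`.
#' @export
gene_scores <- function(fit, genes = fit$genes) {
  sc <- score_genes(fit)
  out <- stats::setNames(rep(0, length(genes)), genes)
  hit <- sc$gene %in% genes
  out[sc$gene[hit]] <- sc$score[hit]
  out
}
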