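#' Differential-gene preselection by two-sample t-test
#'
#' Per-gene two-sample t-test between the two groups; genes with
#' `p < p_threshold` are split by the sign of the mean difference into an
#' up-regulated set (over-expressed in the first factor level) and a
#' down-regulated set. Genes with zero variance in both groups cannot be
#' tested and are excluded (p treated as 1).
#'
#' @param X Expression matrix (genes x samples).
#' @param groups Factor (or coercible) of length `ncol(X)` with exactly two
#'   levels, each with at least 2 samples. The first level plays the role of
#'   the case group ("early recurrence"): genes over-expressed there are
#'   labelled up-regulated.
#' @param p_threshold Selection threshold on the p-value.
#' @param var_equal Pooled-variance t-test instead of the default Welch test.
#' @return List with `up`, `down` (character vectors of gene ids) and `table`,
#'   a tibble `gene, statistic, p_value, mean_diff, direction, selected`.
#' @export
select_differential_genes <- function(X, groups, p_threshold = 0.05,
                                      var_equal = FALSE) {
  X <- as.matrix(X)
  groups <- droplevels(as.factor(groups))
  if (nlevels(groups) != 2) stop("`groups` must have exactly two levels.")
  if (any(table(groups) < 2)) stop("Each group needs at least 2 samples.")
  i1 <- groups == levels(groups)[1]
  res <- apply(X, 1, function(x) {
    out <- tryCatch(stats::t.test(x[i1], x[!i1], var.equal = var_equal),
                    error = function(e) NULL)
    if (is.null(out)) c(NA_real_, 1)
    else c(unname(out$statistic), out$p.value)
  })
  md <- rowMeans(X[, i1, drop = FALSE]) - rowMeans(X[, !i1, drop = FALSE])
  tab <- tibble::tibble(
    gene = rownames(X) %||% as.character(seq_len(nrow(X))),
    statistic = unname(res[1, ]), p_value = unname(res[2, ]),
    mean_diff = unname(md),
    direction = ifelse(md > 0, "up", "down"),
    selected = unname(res[2, ] < p_threshold & !is.na(res[1, ])))
  list(up = tab$gene[tab$selected & tab$direction == "up"],
       down = tab$gene[tab$selected & tab$direction == "down"],
       table = tab)
}

#' Run the two-step module-identification pipeline
#'
#' The composition of the package: motif-guided affinity propagation
#' clustering, per-cluster hypergeometric TF enrichment, then the per-cluster
#' outlier-sum Gibbs sampler restricted to the enriched TFs. Clusters in which
#' no TF is enriched are skipped for sampling (with a message).
#'
#' @inheritParams run_simulation_study
#' @param X Expression matrix (genes x samples).
#' @param W Binary binding matrix (genes x TFs), same genes as `X`.
#' @param design Gibbs design mode, see [gibbs_os()].
#' @param seed Optional seed making the whole run reproducible.
#' @return An object of class `two_step_fit`: `clustering` (`ap_fit`),
#'   `enrichment` (tibble), `gibbs` (named list of `gibbsos_fit`, one per
#'   sampled cluster), `scores` (tibble `cluster, tf, gene, frequency`) and
#'   `gene_scores` (tibble `cluster, gene, score, foreground rankable`).
#' @export
run_two_step <- function(X, W, lambda = 0.2, preference = "min",
                         damping = 0.9, threshold = 0.05, alpha = 0.05,
                         n_iter = 500, burn_in = 100, design = "auto",
                         seed = NULL) {
  X <- as.matrix(X); W <- as.matrix(W)
  if (!identical(rownames(X), rownames(W)))
    stop("`X` and `W` must be aligned on the same gene ids.")
  if (!is.null(seed)) withr::local_seed(seed)
  fit <- mapc(X, W, lambda = lambda, preference = preference,
              damping = damping)
  enr <- enrich_clusters(fit, W, threshold = threshold)
  gibbs <- list()
  scores <- list()
  for (cl in sort(unique(fit$labels))) {
    tfs_cl <- enr$tf[enr$cluster == cl & enr$enriched]
    if (length(tfs_cl) == 0) {
      message("Cluster ", cl, ": no enriched TF; skipped for sampling.")
      next
    }
    genes_cl <- names(fit$labels)[fit$labels == cl]
    pools <- candidate_pools(W, genes = genes_cl, tfs = tfs_cl)
    gfit <- gibbs_os(X, pools, n_iter = n_iter, burn_in = burn_in,
                     alpha = alpha, design = design)
    gibbs[[as.character(cl)]] <- gfit
    scores[[as.character(cl)]] <-
      dplyr::mutate(gfit$frequency, cluster = cl, .before = 1)
  }
  scores <- dplyr::bind_rows(scores)
  gene_sc <- if (nrow(scores) == 0) {
    tibble::tibble(cluster = integer(), gene = character(), score = numeric())
  } else {
    dplyr::arrange(
      dplyr::summarise(dplyr::group_by(scores, .data$cluster, .data$gene),
                       score = max(.data$frequency), .groups = "drop"),
      .data$cluster, dplyr::desc(.data$score))
  }
  structure(list(clustering = fit, enrichment = enr, gibbs = gibbs,
                 scores = scores, gene_scores = gene_sc),
            class = "two_step_fit")
}

#' @export
print.two_step_fit <- function(x, ...) {
  cat("Two-step regulatory-module fit\n")
  cat(sprintf("  clusters: %d   enriched TF pairs: %d   sampled clusters: %d\n",
              length(x$clustering$exemplars), sum(x$enrichment$enriched),
              length(x$gibbs)))
  invisible(x)
}

#' Bootstrap confidence scores for identified TFs
#'
#' Resamples the expression columns with replacement (stratified within each
#' group so every resample remains testable), reruns differential-gene
#' selection and the two-step pipeline on each resample, and reports for each
#' TF the fraction of resamples in which it was identified — i.e. enriched
#' with a [pvalue_to_score()] score at or above the threshold implied by
#' `conf_level` (two-sided: `qnorm(1 - (1 - conf_level)/2)`, so 0.9 gives
#' 1.645). With group labels the up- and down-regulated gene sets are analyzed
#' separately; without them the full gene set is analyzed once per resample.
#' A resample in which some group degenerates to identical columns is redrawn
#' (with a message).
#'
#' @inheritParams run_two_step
#' @inheritParams select_differential_genes
#' @param groups Optional two-group labels; `NULL` skips preselection.
#' @param n_boot Number of bootstrap resamples (default 100).
#' @param conf_level Confidence level defining "identified" (default 0.9).
#' @param min_genes Minimum selected genes per direction for a resample
#'   analysis to run (smaller sets are recorded as identifying no TF).
#' @param seed Optional seed.
#' @return An object of class `bootstrap_report`: `confidence` (tibble
#'   `direction, tf, confidence, n_boot`; `n_boot * confidence` is always an
#'   integer count) and `scores` (tibble `direction, tf, boot, score` of the
#'   per-resample maximum enrichment score, for distribution summaries).
#' @export
bootstrap_confidence <- function(X, W, groups = NULL, n_boot = 100,
                                 conf_level = 0.9, p_threshold = 0.05,
                                 lambda = 0.2, preference = "min",
                                 damping = 0.9, threshold = 0.05,
                                 alpha = 0.05, n_iter = 500, burn_in = 100,
                                 min_genes = 5, seed = NULL) {
  stopifnot(n_boot >= 1, conf_level > 0, conf_level < 1)
  X <- as.matrix(X); W <- as.matrix(W)
  if (!is.null(seed)) withr::local_seed(seed)
  score_cut <- qnorm(1 - (1 - conf_level) / 2)
  tfs <- colnames(W) %||% as.character(seq_len(ncol(W)))
  hits <- list(); sc_rows <- list()

  draw_cols <- function() {
    for (try in 1:100) {
      idx <- if (is.null(groups)) {
        sample(ncol(X), replace = TRUE)
      } else {
        unlist(lapply(split(seq_len(ncol(X)), groups),
                      function(i) sample(i, replace = TRUE)), use.names = FALSE)
      }
      degenerate <- if (is.null(groups)) {
        all(apply(X[, idx, drop = FALSE], 1, function(x) length(unique(x)) == 1))
      } else {
        any(vapply(split(idx, groups[idx]), function(i)
          all(apply(X[, i, drop = FALSE], 1,
                    function(x) length(unique(x)) == 1)), logical(1)))
      }
      if (!degenerate) return(idx)
      message("Degenerate bootstrap resample; redrawing.")
    }
    stop("Could not draw a non-degenerate bootstrap resample.")
  }

  analyze <- function(genes, Xb, direction, b) {
    if (length(genes) < min_genes) return(NULL)
    fit <- suppressMessages(
      run_two_step(Xb[genes, , drop = FALSE], W[genes, , drop = FALSE],
                   lambda = lambda, preference = preference,
                   damping = damping, threshold = threshold, alpha = alpha,
                   n_iter = n_iter, burn_in = burn_in))
    enr <- fit$enrichment
    best <- dplyr::summarise(dplyr::group_by(enr, .data$tf),
                             score = max(.data$score), .groups = "drop")
    list(identified = best$tf[best$score >= score_cut],
         scores = dplyr::mutate(best, direction = direction, boot = b))
  }

  directions <- if (is.null(groups)) "all" else c("up", "down")
  counts <- matrix(0L, length(tfs), length(directions),
                   dimnames = list(tfs, directions))
  for (b in seq_len(n_boot)) {
    idx <- draw_cols()
    Xb <- X[, idx, drop = FALSE]
    sets <- if (is.null(groups)) {
      list(all = rownames(X))
    } else {
      deg <- select_differential_genes(Xb, groups[idx],
                                       p_threshold = p_threshold)
      list(up = deg$up, down = deg$down)
    }
    for (d in names(sets)) {
      res <- analyze(sets[[d]], Xb, d, b)
      if (is.null(res)) next
      counts[res$identified, d] <- counts[res$identified, d] + 1L
      sc_rows[[length(sc_rows) + 1L]] <- res$scores
    }
  }
  confidence <- tidyr::pivot_longer(
    dplyr::mutate(tibble::as_tibble(counts), tf = tfs),
    -dplyr::all_of("tf"), names_to = "direction", values_to = "count")
  confidence <- dplyr::transmute(
    confidence, direction = .data$direction, tf = .data$tf,
    confidence = .data$count / n_boot, n_boot = n_boot)
  structure(list(confidence = confidence,
                 scores = dplyr::bind_rows(sc_rows),
                 conf_level = conf_level, score_cut = score_cut),
            class = "bootstrap_report")
}

#' @export
print.bootstrap_report <- function(x, ...) {
  cat(sprintf("Bootstrap confidence report (%d resamples, confidence level %g, score cut %.3f)\n",
              x$confidence$n_boot[1], x$conf_level, x$score_cut))
  top <- dplyr::slice_max(dplyr::group_by(x$confidence, .data$direction),
                          .data$confidence, n = 3, with_ties = FALSE)
  print(as.data.frame(top))
  invisible(x)
}
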