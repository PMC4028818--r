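#' Tidy a clustering fit
#'
#' @param x An `ap_fit`.
#' @param ... Unused.
#' @return Tibble `gene, cluster, exemplar` (logical flag).
#' @export
tidy.ap_fit <- function(x, ...) {
  genes <- names(x$labels) %||% as.character(seq_along(x$labels))
  tibble::tibble(gene = genes, cluster = unname(x$labels),
                 exemplar = seq_along(x$labels) %in% x$exemplars)
}

#' @rdname tidy.ap_fit
#' @return For `glance`: one-row tibble `n_genes, n_clusters, n_iterations,
#'   converged, net_similarity, lambda`.
#' @export
glance.ap_fit <- function(x, ...) {
  tibble::tibble(n_genes = x$n, n_clusters = length(x$exemplars),
                 n_iterations = x$n_iterations, converged = x$converged,
                 net_similarity = x$net_similarity, lambda = x$lambda)
}

#' Tidy a GibbsOS fit
#'
#' @param x A `gibbsos_fit`.
#' @param ... Unused.
#' @return The per-(TF, gene) sampling-frequency tibble.
#' @export
tidy.gibbsos_fit <- function(x, ...) x$frequency

#' @rdname tidy.gibbsos_fit
#' @export
glance.gibbsos_fit <- function(x, ...) {
  tibble::tibble(n_tfs = nrow(x$trace), n_iter = x$n_iter,
                 burn_in = x$burn_in, design = x$design, alpha = x$alpha,
                 n_candidates = sum(lengths(x$pools)))
}

#' Tidy a two-step pipeline fit
#'
#' @param x A `two_step_fit`.
#' @param ... Unused.
#' @return The per-cluster gene-score tibble (`cluster, gene, score`).
#' @export
tidy.two_step_fit <- function(x, ...) x$gene_scores

#' @rdname tidy.two_step_fit
#' @export
glance.two_step_fit <- function(x, ...) {
  tibble::tibble(n_clusters = length(x$clustering$exemplars),
                 n_sampled_clusters = length(x$gibbs),
                 n_enriched = sum(x$enrichment$enriched),
                 converged = x$clustering$converged)
}

#' Tidy a bootstrap confidence report
#'
#' @param x A `bootstrap_report`.
#' @param ... Unused.
#' @return The `direction, tf, confidence, n_boot` tibble.
#' @export
tidy.bootstrap_report <- function(x, ...) x$confidence

#' Tidy / summarize a simulation study
#'
#' @param x A `grn_study`.
#' @param ... Unused.
#' @return `tidy`: the underlying tidy metric tibble. `glance`: one row with
#'   cell/repetition counts.
#' @export
tidy.grn_study <- function(x, ...) tibble::as_tibble(x)

#' @rdname tidy.grn_study
#' @export
glance.grn_study <- function(x, ...) {
  tibble::tibble(
    n_cells = nrow(unique(x[, c("snr_db", "fp_ratio", "n_samples")])),
    n_reps = max(x$rep), n_metrics = length(unique(x$metric)))
}
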