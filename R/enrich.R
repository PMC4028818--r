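#' Upper-tail hypergeometric enrichment p-value
#'
#' Probability of observing at least `Nb` TF-bound genes in a random cluster of
#' `Nc` genes drawn from a population of `N` genes of which `NB` are bound by
#' the TF:
#' `p = sum_{i=Nb}^{min(NB,Nc)} C(NB,i) C(N-NB, Nc-i) / C(N, Nc)`.
#' Computed through the numerically stable survival function
#' [stats::phyper()]; the literal sum is retained as a test oracle.
#'
#' @param N Population size.
#' @param NB TF-bound genes in the population.
#' @param Nc Cluster size.
#' @param Nb TF-bound genes observed in the cluster.
#' @return The p-value in `[0, 1]`. Vectorized over its arguments.
#' @export
#' @examples
#' hypergeom_pvalue(10, 5, 4, 3) # 55/210
hypergeom_pvalue <- function(N, NB, Nc, Nb) {
  if (any(NB > N) || any(Nc > N) || any(Nb > pmin(NB, Nc)) || any(Nb < 0))
    stop("Impossible counts: need Nb <= min(NB, Nc) and NB, Nc <= N.")
  phyper(Nb - 1, NB, N - NB, Nc, lower.tail = FALSE)
}

#' Convert an enrichment p-value to a bounded normal-quantile score
#'
#' `score = qnorm(1 - p)`, capped above at `cap` to tame the extreme quantiles
#' of very small p-values. The score is monotone decreasing in `p`; `p = 0.5`
#' maps to 0 and `p = 0` is defined as `cap`. Under this convention a
#' confidence level of 0.9 (two-sided) corresponds to the score threshold
#' `qnorm(0.95) = 1.645`.
#'
#' @param p P-values in `(0, 1]` (0 allowed, mapped to `cap`).
#' @param cap Upper limit of the score (default 4).
#' @return Numeric scores.
#' @export
pvalue_to_score <- function(p, cap = 4) {
  if (any(p < 0) || any(p > 1)) stop("`p` must lie in [0, 1].")
  pmin(qnorm(p, lower.tail = FALSE), cap)
}

#' Hypergeometric TF enrichment of one gene cluster
#'
#' Tests every TF for over-representation of its candidate targets inside the
#' cluster, against the background of all genes in the binding matrix.
#'
#' @param cluster Character vector of gene ids (or integer row indices) in the
#'   cluster; must be non-empty and a subset of `rownames(W)`.
#' @param W Binary genes x TFs binding matrix for the whole population.
#' @param threshold Enrichment threshold on the raw p-value (default 0.05).
#' @param adjust Apply Benjamini-Hochberg correction before thresholding
#'   (off by default).
#' @param cap Cap passed to [pvalue_to_score()].
#' @return A tibble with one row per TF, sorted by p-value (ties broken by TF
#'   id): `tf, Nc, Nb, NB, N, p_value, score, enriched`.
#' @export
enrich_cluster <- function(cluster, W, threshold = 0.05, adjust = FALSE,
                           cap = 4) {
  W <- as.matrix(W)
  if (length(cluster) == 0) stop("`cluster` is empty.")
  if (is.numeric(cluster)) cluster <- rownames(W)[cluster]
  if (!all(cluster %in% rownames(W)))
    stop("Some cluster genes are absent from `W`.")
  N <- nrow(W)
  Nc <- length(cluster)
  NB <- colSums(W)
  Nb <- colSums(W[cluster, , drop = FALSE])
  p <- hypergeom_pvalue(N, NB, Nc, Nb)
  padj <- if (adjust) stats::p.adjust(p, "BH") else p
  res <- tibble::tibble(
    tf = colnames(W) %||% as.character(seq_len(ncol(W))),
    Nc = Nc, Nb = as.integer(Nb), NB = as.integer(NB), N = N,
    p_value = unname(p), score = pvalue_to_score(unname(p), cap = cap),
    enriched = unname(padj) <= threshold)
  dplyr::arrange(res, .data$p_value, .data$tf)
}

#' TF enrichment for every cluster of a clustering fit
#'
#' @param clusters An `ap_fit` from [mapc()]/[affinity_propagation()], or a
#'   named vector of cluster labels.
#' @inheritParams enrich_cluster
#' @return A tibble with columns `cluster` plus the columns of
#'   [enrich_cluster()].
#' @export
enrich_clusters <- function(clusters, W, threshold = 0.05, adjust = FALSE,
                            cap = 4) {
  labels <- if (inherits(clusters, "ap_fit")) clusters$labels else clusters
  if (is.null(names(labels))) names(labels) <- rownames(W)
  purrr::map_dfr(sort(unique(labels)), function(cl) {
    dplyr::mutate(
      enrich_cluster(names(labels)[labels == cl], W, threshold = threshold,
                     adjust = adjust, cap = cap),
      cluster = cl, .before = 1)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
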