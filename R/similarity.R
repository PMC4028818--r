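#' Expression similarity: negative squared Euclidean distance
#'
#' `s(i,j) = -||x_i - x_j||^2` between expression rows, the classical affinity
#' propagation similarity for gene expression. Diagonal entries are 0; the
#' preference (self-similarity) is set later by the clustering routine.
#'
#' @param X Numeric genes x samples matrix; at least 2 genes, no missing
#'   values.
#' @return Symmetric genes x genes similarity matrix.
#' @export
expression_similarity <- function(X) {
  X <- as.matrix(X)
  if (nrow(X) < 2) stop("Need at least 2 genes.")
  if (anyNA(X)) stop("`X` contains missing values.")
  S <- -as.matrix(stats::dist(X))^2
  diag(S) <- 0
  S
}

#' Co-regulation similarity from motif-binding rows
#'
#' `s_reg(k,t) = sum_j w(k,j) * w(t,j)`: the number of TFs with candidate
#' bindings to both genes, proportional to the probability that the two genes
#' are co-regulated given the binding evidence.
#'
#' @param W Binary genes x TFs binding matrix.
#' @return Symmetric genes x genes similarity matrix of integer counts.
#' @export
coregulation_similarity <- function(W) {
  W <- as.matrix(W)
  if (!all(W %in% c(0, 1))) stop("`W` must be binary.")
  tcrossprod(W)
}

#' Combined motif-guided similarity
#'
#' Weighted combination `s(i,j) = -(1-lambda)*||x_i - x_j||^2 +
#' lambda * s_reg(i,j)` of expression distance and motif co-regulation. Because
#' the two terms live on very different scales (a squared distance over K
#' samples versus a small binding count), `normalize = TRUE` (default) divides
#' each term by the standard deviation of its off-diagonal entries before
#' weighting, which makes `lambda` comparable across datasets;
#' `normalize = FALSE` gives the literal unscaled combination. The limits are
#' exact regardless of `normalize`: `lambda = 0` returns
#' [expression_similarity()] (the classical expression-only clustering) and
#' `lambda = 1` returns [coregulation_similarity()].
#'
#' @param X Expression matrix (genes x samples).
#' @param W Binding matrix (genes x TFs), same genes in the same order.
#' @param lambda Trade-off in `[0, 1]`; larger values trust the binding data
#'   more. Under heavily contaminated binding data, smaller values (more weight
#'   on expression) are advisable.
#' @param normalize Rescale each term to unit spread before weighting.
#' @return Symmetric genes x genes similarity matrix with attributes `lambda`
#'   and `normalize`.
#' @export
combined_similarity <- function(X, W, lambda = 0.5, normalize = TRUE) {
  stopifnot(lambda >= 0, lambda <= 1)
  X <- as.matrix(X); W <- as.matrix(W)
  if (nrow(X) != nrow(W))
    stop("`X` and `W` must describe the same genes.")
  if (!is.null(rownames(X)) && !is.null(rownames(W)) &&
      !identical(rownames(X), rownames(W)))
    stop("Gene identifiers of `X` and `W` disagree.")
  if (lambda == 0) {
    S <- expression_similarity(X)
  } else if (lambda == 1) {
    S <- coregulation_similarity(W)
  } else {
    E <- expression_similarity(X)
    R <- coregulation_similarity(W)
    if (normalize) {
      off <- upper.tri(E)
      se <- sd(E[off]); sr <- sd(R[off])
      if (se > 0) E <- E / se
      if (sr > 0) R <- R / sr
    }
    S <- (1 - lambda) * E + lambda * R
  }
  attr(S, "lambda") <- lambda
  attr(S, "normalize") <- normalize
  S
}
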