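#' Read and write the package's TSV formats
#'
#' Expression files are TSV with a `gene_id` first column and one column per
#' sample; binding files are TSV of 0/1 with a `gene_id` first column and one
#' column per TF; cluster files carry `gene_id, cluster_id, exemplar_flag`.
#'
#' @param path File path.
#' @param X,W Matrix to write (genes in rows).
#' @name regmodules-io
NULL

#' @rdname regmodules-io
#' @return `read_expression_tsv`/`read_binding_tsv`: a numeric matrix with
#'   gene ids as rownames.
#' @export
read_expression_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' @rdname regmodules-io
#' @export
read_binding_tsv <- function(path) {
  m <- read_expression_tsv(path)
  if (!all(m %in% c(0, 1))) stop("Binding file is not binary.")
  storage.mode(m) <- "integer"
  m
}

write_genes_tsv <- function(M, path) {
  df <- data.frame(gene_id = rownames(M), M, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' @rdname regmodules-io
#' @export
write_expression_tsv <- function(X, path) write_genes_tsv(as.matrix(X), path)

#' @rdname regmodules-io
#' @export
write_binding_tsv <- function(W, path) write_genes_tsv(as.matrix(W), path)

#' Write a simulated dataset to a directory
#'
#' Writes `expression.tsv`, `binding.tsv` and `truth.json` (foreground mask,
#' module labels, generative partition, active TF sets and the configuration
#' echo; the dense matrices A, S and the noise stay in the R object).
#'
#' @param sim A `grn_sim`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "grn_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_expression_tsv(sim$expression, file.path(dir, "expression.tsv"))
  write_binding_tsv(sim$binding, file.path(dir, "binding.tsv"))
  truth <- sim$truth
  jsonlite::write_json(list(
    config = unclass(sim$config),
    foreground_mask = truth$foreground_mask,
    module_labels = truth$module_labels,
    partition = truth$partition,
    active_tfs_per_module = truth$active_tfs_per_module
  ), file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA,
  pretty = TRUE)
  invisible(dir)
}

#' @rdname regmodules-io
#' @param fit An `ap_fit` to write (`write_clusters_tsv`).
#' @export
write_clusters_tsv <- function(fit, path) {
  df <- tidy(fit)
  names(df) <- c("gene_id", "cluster_id", "exemplar_flag")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' @rdname regmodules-io
#' @return `read_clusters_tsv`: named integer vector of cluster labels with
#'   attribute `exemplars`.
#' @export
read_clusters_tsv <- function(path) {
  df <- read.delim(path)
  labels <- stats::setNames(as.integer(df$cluster_id), df$gene_id)
  attr(labels, "exemplars") <- df$gene_id[as.logical(df$exemplar_flag)]
  labels
}
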