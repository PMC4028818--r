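#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same elements,
#' computed from the contingency table `n_ij`:
#' `ARI = (sum C(n_ij,2) - E) / (max - E)` with
#' `E = sum C(n_i.,2) sum C(n_.j,2) / C(n,2)` and
#' `max = (sum C(n_i.,2) + sum C(n_.j,2)) / 2`. The index lies in `[-1, 1]`
#' and equals 1 exactly when the partitions are identical up to relabeling.
#' When the denominator vanishes (both partitions trivial in the same way,
#' hence identical) the index is defined as 1.
#'
#' @param labels_a,labels_b Vectors of cluster labels over the same elements;
#'   if both are named, they are aligned by name.
#' @return The adjusted Rand index.
#' @export
#' @examples
#' adjusted_rand_index(c(1, 1, 2, 2), c(1, 2, 1, 2)) # -0.5
adjusted_rand_index <- function(labels_a, labels_b) {
  if (!is.null(names(labels_a)) && !is.null(names(labels_b))) {
    if (!setequal(names(labels_a), names(labels_b)))
      stop("The two partitions cover different element sets.")
    labels_b <- labels_b[names(labels_a)]
  }
  if (length(labels_a) != length(labels_b))
    stop("The two partitions cover different element sets.")
  n <- length(labels_a)
  tab <- table(labels_a, labels_b)
  sum_ij <- sum(choose(tab, 2))
  sum_i <- sum(choose(rowSums(tab), 2))
  sum_j <- sum(choose(colSums(tab), 2))
  expected <- sum_i * sum_j / choose(n, 2)
  max_index <- (sum_i + sum_j) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}

#' Area under the ROC curve with Mann-Whitney tie handling
#'
#' `AUC = U / (n_pos * n_neg)` where `U` is the Mann-Whitney statistic
#' computed from midranks, so tied scores contribute 1/2. Invariant under any
#' strictly increasing transform of the scores.
#'
#' @param scores Numeric scores, larger = more positive.
#' @param truth Logical (or two-level) vector of true class labels.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, truth) {
  truth <- as.logical(truth)
  if (anyNA(truth) || anyNA(scores)) stop("Missing values in scores or truth.")
  n_pos <- sum(truth); n_neg <- sum(!truth)
  if (n_pos == 0 || n_neg == 0)
    stop("Both classes must be present to compute an AUC.")
  r <- rank(scores)
  (sum(r[truth]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Match clusters to ground-truth foreground modules by majority overlap
#'
#' @param labels Named cluster labels (gene -> cluster id).
#' @param truth Simulation truth (from a `grn_sim`).
#' @return Integer vector, one entry per module: the cluster id sharing the
#'   most foreground genes with that module.
#' @export
match_clusters_to_modules <- function(labels, truth) {
  vapply(seq_along(truth$active_tfs_per_module), function(m) {
    genes <- names(truth$module_labels)[!is.na(truth$module_labels) &
                                          truth$module_labels == m]
    ov <- table(labels[genes])
    as.integer(names(ov)[which.max(ov)])
  }, integer(1))
}

#' Run the full simulation study over a condition grid
#'
#' For every grid cell and repetition: simulate a dataset, cluster it with
#' mAPC and the comparison methods (expression-only affinity propagation,
#' k-means, hierarchical clustering), evaluate clustering ARIs against the
#' generative partition, test TF enrichment per cluster and evaluate
#' cluster-wise TF-identification AUC, then run the per-cluster Gibbs sampler
#' (mAPC-GibbsOS) and the pool-wide sampler (GibbsOS, no clustering) and
#' evaluate target-gene AUCs against the foreground labels. Every metric is
#' returned as one tidy row.
#'
#' @param grid Data frame with columns `snr_db`, `fp_ratio`, `n_samples`; one
#'   row per condition cell. See [benchmark_grid()] for the bundled benchmarks.
#' @param n_reps Repetitions per cell.
#' @param seed Base seed; repetition r of cell g uses `seed + 1000*g + r`.
#' @param config Template [simulation_config()] supplying all non-grid
#'   parameters.
#' @param lambda,preference,damping mAPC settings.
#' @param threshold Enrichment threshold selecting the TFs sampled per
#'   cluster.
#' @param alpha,n_iter,burn_in Gibbs sampler settings.
#' @param metrics Character subset of `c("clustering", "tf", "targets")`
#'   selecting what to compute.
#' @return A tibble of class `grn_study`: columns `snr_db, fp_ratio,
#'   n_samples, rep, metric, method, cluster, value` (`cluster` is the module
#'   index for per-cluster metrics, NA otherwise).
#' @export
run_simulation_study <- function(grid = benchmark_grid("fp"), n_reps = 5,
                                 seed = 1, config = simulation_config(),
                                 lambda = 0.2, preference = "min",
                                 damping = 0.9, threshold = 0.05,
                                 alpha = 0.05, n_iter = 500, burn_in = 100,
                                 metrics = c("clustering", "tf", "targets")) {
  metrics <- match.arg(metrics, several.ok = TRUE)
  grid <- as.data.frame(grid)
  stopifnot(all(c("snr_db", "fp_ratio", "n_samples") %in% names(grid)))
  rows <- list()
  for (g in seq_len(nrow(grid))) {
    for (r in seq_len(n_reps)) {
      cell <- grid[g, ]
      cfg <- config
      cfg$snr_db <- cell$snr_db
      cfg$fp_ratio <- cell$fp_ratio
      cfg$n_samples <- as.integer(cell$n_samples)
      cfg$seed <- as.integer(seed + 1000 * g + r)
      res <- evaluate_one(cfg, lambda = lambda, preference = preference,
                          damping = damping, threshold = threshold,
                          alpha = alpha, n_iter = n_iter, burn_in = burn_in,
                          metrics = metrics)
      rows[[length(rows) + 1L]] <-
        dplyr::mutate(res, snr_db = cell$snr_db, fp_ratio = cell$fp_ratio,
                      n_samples = cell$n_samples, rep = r, .before = 1)
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("grn_study", class(out))
  out
}

# One simulated dataset -> tidy metric rows. The whole evaluation (not just
# the simulation) runs under the repetition seed so k-means restarts and the
# Gibbs sweeps are reproducible.
evaluate_one <- function(cfg, lambda, preference, damping, threshold, alpha,
                         n_iter, burn_in, metrics) {
  if (!is.null(cfg$seed)) withr::local_seed(cfg$seed + 1L)
  sim <- simulate_regulatory_data(cfg)
  truth <- sim$truth
  part <- true_partition(sim)
  out <- list()
  add <- function(metric, method, cluster, value)
    out[[length(out) + 1L]] <<- tibble::tibble(
      metric = metric, method = method, cluster = cluster, value = value)

  fit <- mapc(sim$expression, sim$binding, lambda = lambda,
              preference = preference, damping = damping)
  if ("clustering" %in% metrics) {
    add("ari", "mAPC", NA_integer_,
        adjusted_rand_index(fit$labels, part))
    apc <- mapc(sim$expression, sim$binding, lambda = 0,
                preference = preference, damping = damping)
    add("ari", "APC", NA_integer_,
        adjusted_rand_index(apc$labels, part))
    k <- length(unique(part))
    km <- stats::kmeans(sim$expression, centers = k, nstart = 5)
    add("ari", "kmeans", NA_integer_,
        adjusted_rand_index(stats::setNames(km$cluster, rownames(sim$expression)),
                            part))
    hc <- stats::cutree(stats::hclust(stats::dist(sim$expression), "ward.D2"), k)
    add("ari", "hierarchical", NA_integer_,
        adjusted_rand_index(stats::setNames(hc, rownames(sim$expression)), part))
  }

  if (any(c("tf", "targets") %in% metrics)) {
    enr <- enrich_clusters(fit, sim$binding, threshold = threshold)
    matched <- match_clusters_to_modules(fit$labels, truth)
    for (m in seq_along(matched)) {
      cl <- matched[m]
      rows_cl <- enr[enr$cluster == cl, ]
      if ("tf" %in% metrics) {
        pos <- rows_cl$tf %in% truth$active_tfs_per_module[[m]]
        add("tf_auc", "mAPC", m, roc_auc(-rows_cl$p_value, pos))
      }
      if ("targets" %in% metrics) {
        genes_cl <- names(fit$labels)[fit$labels == cl]
        tfs_cl <- rows_cl$tf[rows_cl$enriched]
        if (length(tfs_cl) == 0) {
          add("target_auc", "mAPC-GibbsOS", m, NA_real_)
        } else {
          pools <- candidate_pools(sim$binding, genes = genes_cl,
                                   tfs = tfs_cl)
          gfit <- gibbs_os(sim$expression, pools, n_iter = n_iter,
                           burn_in = burn_in, alpha = alpha)
          # module-m genes against the whole population: genes the cluster
          # failed to capture score 0, so cluster coverage bounds the AUC
          sc <- gene_scores(gfit, rownames(sim$expression))
          pos <- !is.na(truth$module_labels) & truth$module_labels == m
          add("target_auc", "mAPC-GibbsOS", m, roc_auc(sc, pos))
        }
      }
    }
    if ("targets" %in% metrics) {
      pools_all <- candidate_pools(sim$binding)
      gfit <- gibbs_os(sim$expression, pools_all, n_iter = n_iter,
                       burn_in = burn_in, alpha = alpha)
      sc <- gene_scores(gfit, rownames(sim$expression))
      add("target_auc", "GibbsOS", NA_integer_,
          roc_auc(sc, truth$foreground_mask))
    }
  }
  dplyr::bind_rows(out)
}

#' Benchmark condition grids
#'
#' The three condition grids of the bundled simulation benchmark:
#' `"fp"` varies the false-positive ratio (0.5, 1, 1.5) at SNR 5 dB,
#' `"snr"` varies the SNR (0, 5, 10 dB) at FP ratio 1, and `"samples"` varies
#' the sample size (5, 15, 25, 35, 45) at SNR 5 dB, FP ratio 0.5. All use 20
#' samples unless varied.
#'
#' @param which One of `"fp"`, `"snr"`, `"samples"`, or `"clustering"` (the
#'   union of the fp and snr cells, i.e. the five cells on which clustering
#'   and TF identification are evaluated).
#' @return Tibble with columns `snr_db`, `fp_ratio`, `n_samples`.
#' @export
benchmark_grid <- function(which = c("fp", "snr", "samples", "clustering")) {
  which <- match.arg(which)
  switch(which,
    fp = tibble::tibble(snr_db = 5, fp_ratio = c(0.5, 1, 1.5),
                        n_samples = 20),
    snr = tibble::tibble(snr_db = c(0, 5, 10), fp_ratio = 1, n_samples = 20),
    samples = tibble::tibble(snr_db = 5, fp_ratio = 0.5,
                             n_samples = c(5, 15, 25, 35, 45)),
    clustering = tibble::tibble(
      snr_db = c(10, 5, 5, 5, 0), fp_ratio = c(1, 0.5, 1, 1.5, 1),
      n_samples = 20))
}

#' Min/median/max summary of a simulation study
#'
#' @param object A `grn_study` tibble from [run_simulation_study()].
#' @param ... Unused.
#' @return Tibble with one row per (cell, metric, method, cluster) carrying
#'   `min`, `median`, `max` and `n_reps` over repetitions.
#' @export
summary.grn_study <- function(object, ...) {
  dplyr::summarise(
    dplyr::group_by(object, .data$snr_db, .data$fp_ratio, .data$n_samples,
                    .data$metric, .data$method, .data$cluster),
    min = min(.data$value, na.rm = TRUE),
    median = median(.data$value, na.rm = TRUE),
    max = max(.data$value, na.rm = TRUE),
    n_reps = dplyr::n(), .groups = "drop")
}
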