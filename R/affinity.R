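#' Affinity propagation clustering
#'
#' Standard affinity propagation by message passing. Responsibilities and
#' availabilities are updated with damping until the exemplar set is stable
#' for `conv_iter` consecutive iterations:
#' \describe{
#'   \item{responsibility}{`r(i,k) <- s(i,k) - max_{k' != k}[a(i,k') + s(i,k')]`}
#'   \item{availability}{`a(i,k) <- min(0, r(k,k) + sum_{i' not in {i,k}}
#'     max(0, r(i',k)))`, with `a(k,k) <- sum_{i' != k} max(0, r(i',k))`}
#' }
#' Exemplars are the points with `r(k,k) + a(k,k) > 0`; every point is then
#' assigned to its most similar exemplar (exemplars to themselves), and within
#' each cluster the exemplar is refined to the member with the greatest summed
#' similarity to the other members.
#'
#' The updates are deterministic: identical inputs give identical output. A
#' tiny seeded symmetric tie-breaking jitter can be requested for degenerate
#' similarity matrices but is off by default.
#'
#' @param S Square (symmetric) similarity matrix.
#' @param preference Self-similarity controlling how many exemplars emerge:
#'   `"median"` (default, the median of the off-diagonal similarities),
#'   `"min"`, or a numeric scalar / per-point vector.
#' @param damping Damping factor in `[0.5, 1)`.
#' @param max_iter Maximum number of message-passing iterations.
#' @param conv_iter Iterations of exemplar-set stability required to declare
#'   convergence.
#' @param noise Add a tiny seeded jitter (`1e-12` scale) to break exact ties.
#' @param seed Seed for the jitter; ignored when `noise = FALSE`.
#' @return An object of class `ap_fit` with elements `labels` (named integer
#'   cluster ids, 1..k), `exemplars` (named indices of the exemplar of each
#'   cluster), `n_iterations`, `converged`, `preference`, `net_similarity`
#'   (the value of the exemplar-set objective
#'   `sum_i s(i, exemplar(i)) + sum_k preference(k)`).
#' @export
affinity_propagation <- function(S, preference = "median", damping = 0.9,
                                 max_iter = 1000L, conv_iter = 50L,
                                 noise = FALSE, seed = NULL) {
  S <- as.matrix(S)
  n <- nrow(S)
  if (n != ncol(S)) stop("`S` must be square.")
  if (anyNA(S)) stop("`S` contains missing values.")
  if (damping < 0.5 || damping >= 1) stop("`damping` must be in [0.5, 1).")
  if (n == 1) {
    return(new_ap_fit(labels = stats::setNames(1L, rownames(S)),
                      exemplars = stats::setNames(1L, rownames(S)),
                      n_iterations = 0L, converged = TRUE,
                      preference = 0, S = S))
  }

  pref <- resolve_preference(preference, S)
  diag(S) <- pref
  if (noise) {
    if (!is.null(seed)) withr::local_seed(seed)
    J <- matrix(rnorm(n * n), n, n) * 1e-12 * (max(abs(S)) + 1)
    S <- S + (J + t(J)) / 2
  }

  R <- matrix(0, n, n)
  A <- matrix(0, n, n)
  e_hist <- matrix(FALSE, n, conv_iter)
  converged <- FALSE
  it <- 0L
  idx <- seq_len(n)
  for (it in seq_len(max_iter)) {
    # responsibilities
    AS <- A + S
    max1_pos <- max.col(AS, ties.method = "first")
    max1 <- AS[cbind(idx, max1_pos)]
    AS2 <- AS
    AS2[cbind(idx, max1_pos)] <- -Inf
    max2 <- AS2[cbind(idx, max.col(AS2, ties.method = "first"))]
    Rnew <- S - max1
    Rnew[cbind(idx, max1_pos)] <- S[cbind(idx, max1_pos)] - max2
    R <- damping * R + (1 - damping) * Rnew
    # availabilities
    Rp <- pmax(R, 0)
    diag(Rp) <- diag(R)
    cs <- colSums(Rp)
    Anew <- matrix(cs, n, n, byrow = TRUE) - Rp
    Anew[Anew > 0] <- 0
    diag(Anew) <- cs - diag(R)
    A <- damping * A + (1 - damping) * Anew

    e <- (diag(A) + diag(R)) > 0
    e_hist[, (it - 1L) %% conv_iter + 1L] <- e
    if (it >= conv_iter && any(e)) {
      stable <- all(rowSums(e_hist) %in% c(0L, conv_iter))
      if (stable) { converged <- TRUE; break }
    }
  }
  ex <- which((diag(A) + diag(R)) > 0)
  if (length(ex) == 0) {
    warning("Affinity propagation produced no exemplar; returning the best ",
            "single-exemplar assignment.")
    ex <- which.max(diag(A) + diag(R))
    converged <- FALSE
  }
  if (!converged)
    warning("Affinity propagation did not converge in ", it, " iterations.")

  assign <- ex[max.col(S[, ex, drop = FALSE], ties.method = "first")]
  assign[ex] <- ex
  # refine each exemplar to the member maximizing within-cluster similarity
  for (k in unique(assign)) {
    members <- which(assign == k)
    if (length(members) > 1) {
      Sm <- S[members, members, drop = FALSE]
      diag(Sm) <- 0
      best <- members[which.max(colSums(Sm))]
      assign[members] <- best
    }
  }
  exemplars <- sort(unique(assign))
  labels <- match(assign, exemplars)
  non_ex <- setdiff(idx, exemplars)
  net <- sum(S[cbind(non_ex, assign[non_ex])]) +
    sum(pref_vec(pref, n)[exemplars])
  nm <- rownames(S)
  new_ap_fit(labels = stats::setNames(as.integer(labels), nm),
             exemplars = stats::setNames(as.integer(exemplars),
                                         if (!is.null(nm)) nm[exemplars]),
             n_iterations = it, converged = converged, preference = pref,
             S = S, net_similarity = net)
}

resolve_preference <- function(preference, S) {
  off <- S[row(S) != col(S)]
  if (is.character(preference)) {
    switch(match.arg(preference, c("median", "min")),
           median = median(off),
           min = min(off))
  } else {
    stopifnot(is.numeric(preference),
              length(preference) %in% c(1L, nrow(S)))
    preference
  }
}

pref_vec <- function(pref, n) if (length(pref) == 1) rep(pref, n) else pref

new_ap_fit <- function(labels, exemplars, n_iterations, converged, preference,
                       S, net_similarity = NA_real_, lambda = NA_real_) {
  structure(list(labels = labels, exemplars = exemplars,
                 n_iterations = n_iterations, converged = converged,
                 preference = preference, net_similarity = net_similarity,
                 lambda = lambda, n = length(labels)),
            class = "ap_fit")
}

#' @export
print.ap_fit <- function(x, ...) {
  cat(sprintf("Affinity propagation fit: %d points, %d clusters (%s after %d iterations)\n",
              x$n, length(x$exemplars),
              if (x$converged) "converged" else "NOT converged",
              x$n_iterations))
  if (!is.na(x$lambda)) cat(sprintf("  motif-guided, lambda = %g\n", x$lambda))
  cat("  cluster sizes:", paste(tabulate(x$labels), collapse = ", "), "\n")
  invisible(x)
}

#' Motif-guided affinity propagation clustering (mAPC)
#'
#' Clusters genes into co-regulated modules by affinity propagation on the
#' [combined_similarity()] of expression and motif-binding data. With
#' `lambda = 0` this is exactly classical affinity propagation on expression
#' alone; with `lambda = 1` clustering depends on the binding data only.
#'
#' Defaults are tuned for module discovery: `lambda = 0.2` keeps the
#' clustering expression-led with binding as a guide (candidate binding data
#' carry false positives, and after normalization the binding term is far
#' less noisy than expression, so equal weighting would let it dominate), and
#' `preference = "min"` puts affinity propagation in its few-clusters regime,
#' appropriate when the expected number of modules is small relative to the
#' number of genes.
#'
#' @inheritParams combined_similarity
#' @inheritParams affinity_propagation
#' @param ... Passed on to [affinity_propagation()].
#' @return An `ap_fit` (see [affinity_propagation()]) with the `lambda` used.
#' @export
#' @examples
#' sim <- simulate_regulatory_data(simulation_config(
#'   n_foreground = 20, n_background = 20, n_tfs = 16, n_samples = 10,
#'   n_modules = 2, tfs_per_module = 4, gene_degree = 2, seed = 1))
#' fit <- mapc(sim$expression, sim$binding)
#' table(fit$labels)
mapc <- function(X, W, lambda = 0.2, normalize = TRUE, preference = "min",
                 damping = 0.9, ...) {
  S <- combined_similarity(X, W, lambda = lambda, normalize = normalize)
  fit <- affinity_propagation(S, preference = preference, damping = damping,
                              ...)
  fit$lambda <- lambda
  fit
}

#' Exhaustive exemplar-set search (brute-force reference)
#'
#' Maximizes the affinity propagation objective
#' `sum_{i not exemplar} max_{k in E} s(i,k) + sum_{k in E} preference(k)`
#' over every non-empty exemplar subset. Only feasible for small n; intended
#' as an independent check of [affinity_propagation()].
#'
#' @inheritParams affinity_propagation
#' @return List with `net_similarity`, `exemplars`, `labels`.
#' @export
exact_exemplar_search <- function(S, preference = "median") {
  S <- as.matrix(S)
  n <- nrow(S)
  if (n > 12) stop("Exhaustive search is limited to n <= 12.")
  pref <- pref_vec(resolve_preference(preference, S), n)
  best <- -Inf; best_E <- NULL
  for (mask in seq_len(2^n - 1)) {
    E <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    rest <- setdiff(seq_len(n), E)
    val <- sum(pref[E])
    if (length(rest))
      val <- val + sum(apply(S[rest, E, drop = FALSE], 1, max))
    if (val > best) { best <- val; best_E <- E }
  }
  assign <- best_E[max.col(S[, best_E, drop = FALSE], ties.method = "first")]
  assign[best_E] <- best_E
  list(net_similarity = best, exemplars = best_E,
       labels = match(assign, sort(unique(assign))))
}
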