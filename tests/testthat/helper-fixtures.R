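# Shared fixtures and brute-force oracles, all generated in code.

# small, fully valid simulator configuration for fast tests
tiny_config <- function(seed = 1, ...) {
  args <- list(n_foreground = 20, n_background = 20, n_tfs = 16,
               n_samples = 12, n_modules = 2, tfs_per_module = 4,
               gene_degree = 2, snr_db = 10, fp_ratio = 0.5, seed = seed)
  args[names(list(...))] <- list(...)
  do.call(simulation_config, args)
}

# literal double-loop versions of the similarity measures
brute_expression_similarity <- function(X) {
  n <- nrow(X)
  S <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    S[i, j] <- -sum((X[i, ] - X[j, ])^2)
  S
}

brute_coregulation_similarity <- function(W) {
  n <- nrow(W)
  S <- matrix(0, n, n)
  for (k in seq_len(n)) for (t in seq_len(n))
    S[k, t] <- sum(W[k, ] * W[t, ])
  S
}

# literal-sum hypergeometric upper tail
brute_hypergeom <- function(N, NB, Nc, Nb) {
  i <- Nb:min(NB, Nc)
  sum(choose(NB, i) * choose(N - NB, Nc - i)) / choose(N, Nc)
}

# exact stationary distribution of the two-TF Gibbs kernel: states are
# (seed of TF 1, seed of TF 2); one sweep updates TF 1 given TF 2, then TF 2
# given the new TF 1.
gibbs_stationary_2tf <- function(X, pools, alpha = 0.05) {
  K1 <- length(pools[[1]]); K2 <- length(pools[[2]])
  states <- expand.grid(a = seq_len(K1), b = seq_len(K2))
  P <- matrix(0, nrow(states), nrow(states))
  for (s in seq_len(nrow(states))) {
    seeds <- c(pools[[1]][states$a[s]], pools[[2]][states$b[s]])
    w1 <- conditional_weights(1, seeds, X, pools, alpha = alpha)
    for (a2 in seq_len(K1)) {
      seeds2 <- c(pools[[1]][a2], seeds[2])
      w2 <- conditional_weights(2, seeds2, X, pools, alpha = alpha)
      for (b2 in seq_len(K2)) {
        t <- which(states$a == a2 & states$b == b2)
        P[s, t] <- w1[a2] * w2[b2]
      }
    }
  }
  e <- eigen(t(P))
  v <- Re(e$vectors[, which.min(abs(e$values - 1))])
  pi_st <- v / sum(v)
  list(states = states, P = P, pi = pi_st,
       marginal_1 = tapply(pi_st, states$a, sum),
       marginal_2 = tapply(pi_st, states$b, sum))
}

# deterministic toy expression set for sampler tests: two TFs with disjoint
# 3-gene candidate pools; genes 1 and 4 are the "true" seeds that the other
# candidates follow.
toy_gibbs_problem <- function(K = 12, noise = 0.3, seed = 42) {
  withr::with_seed(seed, {
    s1 <- rnorm(K); s2 <- rnorm(K)
    X <- rbind(
      g1 = s1,
      g2 = s1 * 0.9 + rnorm(K, sd = noise),
      g3 = rnorm(K),
      g4 = s2,
      g5 = s2 * 0.8 + rnorm(K, sd = noise),
      g6 = rnorm(K))
  })
  list(X = X, pools = list(tfA = 1:3, tfB = 4:6))
}
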