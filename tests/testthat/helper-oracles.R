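# Independent oracles and small fixture builders shared across test files.

# Amari inter-symbol interference of a gain matrix P = W %*% (mixing chain);
# 0 for a perfect (scaled permutation) separation, grows with cross-talk.
amari_index <- function(P) {
  P <- abs(P)
  n <- nrow(P)
  rows <- sum(rowSums(P / apply(P, 1L, max)) - 1)
  cols <- sum(colSums(t(t(P) / apply(P, 2L, max))) - 1)
  (rows + cols) / (2 * n * (n - 1))
}

# Brute-force minimum-cost assignment by enumerating all permutations.
brute_force_assignment <- function(cost) {
  n <- nrow(cost)
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    out
  }
  best <- NULL; best_cost <- Inf
  for (p in perms(seq_len(n))) {
    cst <- sum(cost[cbind(seq_len(n), p)])
    if (cst < best_cost) { best_cost <- cst; best <- p }
  }
  list(assignment = best, cost = best_cost)
}

# A random multi-target site list with known pooled rows, for partition tests.
random_sites <- function(n = 60L, d = 3L, V = 1L, S = 3L, seed = 1L) {
  set.seed(seed)
  X <- cbind(matrix(rnorm(n * d), n, d), 1)
  colnames(X) <- c(paste0("x", seq_len(d)), "intercept")
  Y <- matrix(rnorm(n * V), n, V)
  pooled <- site_dataset("pooled", X, Y)
  partition_dataset(pooled, rep(1 / S, S), seed = seed + 1L)
}
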