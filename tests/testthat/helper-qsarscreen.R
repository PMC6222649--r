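# Shared fixtures and independent oracles for the test suite.

# A small linear dataset with two informative descriptors among noise.
make_planted_ds <- function(n = 100, p_noise = 20, noise_sd = 0.1, seed = 1,
                            coefs = c(1, 1.5, -2)) {
  spec <- synthetic_spec(n, p_noise + 2L,
                         informative_indices = c(1L, 2L),
                         true_coefficients = coefs,
                         noise_sd = noise_sd, seed = seed)
  gen_linear_dataset(spec)
}

# Exhaustive best-subset search: the brute-force oracle for bmlr_search.
# Returns the best descriptor-name subset per k (by R2), honouring the
# pairwise intercorrelation cap.
exhaustive_best_subset <- function(table, y, k_max, max_intercorrelation = 0.8) {
  C <- abs(cor(table))
  p <- ncol(table)
  out <- list()
  for (k in 2:k_max) {
    best_r2 <- -Inf
    best <- NULL
    for (idx in asplit(combn(p, k), 2)) {
      if (max(C[idx, idx][upper.tri(diag(k))]) > max_intercorrelation) next
      fit <- stats::lm.fit(cbind(1, table[, idx, drop = FALSE]), y)
      r2 <- 1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
      if (r2 > best_r2) {
        best_r2 <- r2
        best <- colnames(table)[idx]
      }
    }
    out[[paste0("k", k)]] <- list(names = best, r2 = best_r2)
  }
  out
}

# Explicit n-fold refit loop: the oracle for the hat-matrix LOO shortcut.
loo_r2_refit <- function(X, y) {
  n <- nrow(X)
  preds <- vapply(seq_len(n), function(i) {
    fit <- stats::lm.fit(cbind(1, X[-i, , drop = FALSE]), y[-i])
    drop(c(1, X[i, ]) %*% fit$coefficients)
  }, numeric(1))
  1 - sum((y - preds)^2) / sum((y - mean(y))^2)
}

# Conditions of the standard nonlinear benchmark used across the suite.
nonlinear_benchmark <- function(seed = 11) {
  gen_nonlinear_dataset(synthetic_spec(150, 8, noise_sd = 0.1, seed = seed))
}

ann_benchmark_config <- function(seed = 5) {
  train_config(eta = 0.05, alpha = 0.5, max_epochs = 2500, patience = 300,
               seed = seed)
}
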