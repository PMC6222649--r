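test_that("fit_ols recovers an exact linear relationship", {
  x <- matrix(seq(0, 10, length.out = 20), ncol = 1,
              dimnames = list(NULL, "x"))
  m <- fit_ols(x, 1 + 2 * x[, 1])
  expect_equal(unname(m$B), c(1, 2), tolerance = 1e-10)
  expect_equal(m$R2, 1, tolerance = 1e-12)
})

test_that("fit_ols matches the reference implementation on random instances", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- 40; p <- 4
    X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("x", 1:p)))
    y <- rnorm(n)
    m <- fit_ols(X, y)
    ref <- stats::lm(y ~ X)
    s <- summary(ref)
    expect_equal(unname(m$B), unname(coef(ref)), tolerance = 1e-8)
    expect_equal(unname(m$SE), unname(s$coefficients[, 2]), tolerance = 1e-8)
    expect_equal(unname(m$t_stats), unname(s$coefficients[, 3]),
                 tolerance = 1e-8)
    expect_equal(m$R2, s$r.squared, tolerance = 1e-10)
    expect_equal(m$s2, s$sigma^2, tolerance = 1e-10)
    expect_equal(m$F, unname(s$fstatistic[1]), tolerance = 1e-8)
    # F from (R2, N, k) is consistent with F from sums of squares
    rss <- sum(m$residuals^2)
    ssreg <- sum((m$fitted - mean(y))^2)
    f_ss <- (ssreg / p) / (rss / (n - p - 1))
    expect_equal(m$F, f_ss, tolerance = 1e-10)
  }
})

test_that("rank-deficient descriptor matrices are rejected naming the collinear column", {
  X <- cbind(a = 1:20, b = 2 * (1:20))
  expect_error(fit_ols(X, rnorm(20)), "collinear.*b")
})

test_that("hat-matrix leave-one-out equals the explicit refit loop", {
  set.seed(7)
  X <- matrix(rnorm(30 * 3), 30, 3, dimnames = list(NULL, paste0("x", 1:3)))
  y <- X[, 1] - X[, 2] + rnorm(30, 0, 0.5)
  expect_equal(loo_r2(X, y), loo_r2_refit(X, y), tolerance = 1e-10)
})

test_that("leave-one-out R2 is perfect on noiseless data and bounded by R2 across random datasets", {
  x <- matrix(1:20, ncol = 1, dimnames = list(NULL, "x"))
  expect_equal(loo_r2(x, 3 + 0.5 * x[, 1]), 1, tolerance = 1e-10)
  for (seed in 1:100) {
    set.seed(seed)
    X <- matrix(rnorm(25 * 2), 25, 2, dimnames = list(NULL, c("a", "b")))
    y <- rnorm(25)
    m <- fit_ols(X, y)
    expect_lte(m$R2_cv, m$R2 + 1e-12)
    expect_equal(m$R2_cv, loo_r2(X, y), tolerance = 1e-12)
  }
})

test_that("BMLR beam search equals exhaustive best-subset enumeration", {
  for (seed in 1:3) {
    set.seed(seed)
    n <- 60; p <- 10
    D <- matrix(runif(n * p, 0, 10), n, p,
                dimnames = list(NULL, sprintf("D%02d", 1:p)))
    y <- 0.8 * D[, 2] - 0.5 * D[, 7] + 0.3 * D[, 4] + rnorm(n, 0, 0.5)
    res <- bmlr_search(D, y, k_max = 4)
    oracle <- exhaustive_best_subset(D, y, k_max = 4)
    prev_r2 <- -Inf
    for (k in 2:4) {
      key <- paste0("k", k)
      expect_setequal(res$models[[key]]$descriptor_names, oracle[[key]]$names)
      expect_equal(res$models[[key]]$R2, oracle[[key]]$r2, tolerance = 1e-10)
      expect_gte(oracle[[key]]$r2, prev_r2)  # nested-model monotonicity
      prev_r2 <- oracle[[key]]$r2
    }
  }
})

test_that("BMLR finds a planted two-descriptor signal among noise", {
  ds <- make_planted_ds(n = 100, p_noise = 20, noise_sd = 0.1, seed = 5)
  res <- bmlr_search(ds$descriptors, ds$activity, k_max = 2)
  expect_setequal(res$models$k2$descriptor_names,
                  colnames(ds$descriptors)[1:2])
})

test_that("BMLR honours the intercorrelation cap and fails cleanly without admissible pairs", {
  set.seed(2)
  base <- runif(80, 0, 10)
  D <- cbind(a = base + rnorm(80, 0, 0.01), b = base + rnorm(80, 0, 0.01),
             c = base + rnorm(80, 0, 0.01))
  expect_error(bmlr_search(D, rnorm(80), k_max = 2,
                           max_intercorrelation = 0.8),
               "no admissible")
})

test_that("leverage reduction removes a planted extreme point first and is deterministic", {
  set.seed(11)
  X <- matrix(runif(50, 0, 10), ncol = 1, dimnames = list(NULL, "x"))
  y <- 1 + 0.5 * X[, 1] + rnorm(50, 0, 0.2)
  X[50, 1] <- 500  # extreme descriptor outlier
  red <- leverage_reduce(X, y)
  expect_identical(red$removed_ids[1], "R0050")
  none <- leverage_reduce(X, y, threshold_multiplier = Inf)
  expect_identical(none$removed_ids, character(0))
  expect_identical(nrow(none$descriptors), 50L)
  again <- leverage_reduce(X, y)
  expect_identical(red$removed_ids, again$removed_ids)
})

test_that("leverage reduction respects the size floor", {
  set.seed(3)
  X <- matrix(c(runif(18, 0, 1), 50, 100), ncol = 1,
              dimnames = list(NULL, "x"))
  y <- rnorm(20)
  expect_warning(red <- leverage_reduce(X, y, threshold_multiplier = 0.1,
                                        floor_fraction = 0.9),
                 "floor")
  expect_gte(nrow(red$descriptors), 18L)
})

test_that("abc_split partitions by sorted rank with stable tie handling", {
  lab9 <- abc_split(rnorm(9))
  expect_equal(as.integer(table(lab9)), rep(3L, 3))
  lab101 <- abc_split(rnorm(101))
  expect_equal(as.integer(table(lab101)), c(34L, 34L, 33L))
  # every index labelled exactly once
  expect_identical(length(lab101), 101L)
  expect_false(anyNA(lab101))
  # ties broken by original index: tied values take consecutive subset labels
  y <- c(1, 2, 2, 2, 3)
  expect_identical(as.character(abc_split(y))[2:4], c("B", "C", "A"))
})

test_that("ABC validation is exact on noiseless data and averages the fold predictions", {
  set.seed(8)
  D <- matrix(runif(60 * 3, 0, 10), 60, 3,
              dimnames = list(NULL, c("a", "b", "c")))
  y <- 2 + D[, 1] - 0.5 * D[, 2] + 0.1 * D[, 3]
  rep_ <- abc_validate(D, y, c("a", "b", "c"))
  expect_equal(rep_$folds$r2_fit, rep(1, 3), tolerance = 1e-10)
  expect_equal(rep_$folds$r2_cv, rep(1, 3), tolerance = 1e-10)
  expect_equal(rep_$folds$r2_pred, rep(1, 3), tolerance = 1e-10)
  expect_equal(rep_$r2_pred_avg, mean(rep_$folds$r2_pred))
  expect_identical(rep_$folds$train, c("AB", "BC", "CA"))
  expect_identical(rep_$folds$test, c("C", "A", "B"))
})

test_that("planted coefficients are recovered within 3 standard errors in most replicates", {
  hits <- 0L
  n_rep <- 100L
  for (r in seq_len(n_rep)) {
    ds <- make_planted_ds(n = 150, p_noise = 3, noise_sd = 0.1, seed = 1000 + r)
    m <- fit_ols(ds$descriptors[, 1:2], ds$activity)
    truth <- ds$truth$true_coefficients
    ok <- all(abs(m$B - truth) <= 3 * m$SE)
    hits <- hits + ok
  }
  expect_gte(hits / n_rep, 0.95)
})
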