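test_that("activity-stratified split reproduces the published validation counts", {
  for (cse in list(c(101, 20), c(133, 26), c(151, 30))) {
    n <- cse[1]
    ds <- gen_linear_dataset(synthetic_spec(n, 2, informative_indices = 1L,
                                            true_coefficients = c(0, 1),
                                            noise_sd = 0.5, seed = n))
    sp <- train_val_split(ds, step = 5)
    expect_identical(length(sp$val_index), as.integer(cse[2]))
    expect_identical(length(sp$train_index), as.integer(n - cse[2]))
    # partition, identifiers preserved
    expect_setequal(c(rownames(sp$train$descriptors),
                      rownames(sp$validation$descriptors)),
                    rownames(ds$descriptors))
  }
})

test_that("validation picks every step-th compound in ascending activity order", {
  ds <- gen_linear_dataset(synthetic_spec(10, 2, informative_indices = 1L,
                                          true_coefficients = c(0, 1),
                                          noise_sd = 1, seed = 6))
  sp <- train_val_split(ds, step = 5)
  ranks <- rank(ds$activity, ties.method = "first")
  expect_setequal(ranks[sp$val_index], c(5, 10))
  expect_error(train_val_split(ds, step = 4), "step must be 3 or 5")
  expect_silent(train_val_split(ds, step = 2, allow_any_step = TRUE))
  expect_error(train_val_split(ds, step = 5, allow_any_step = TRUE) -> x,
               NA)
  small <- gen_linear_dataset(synthetic_spec(7, 2, informative_indices = 1L,
                                             true_coefficients = c(0, 1),
                                             noise_sd = 1, seed = 6))
  expect_error(train_val_split(small, step = 5), "at least")
})

test_that("network initialization is seeded, sized by the architecture, and zero-biased", {
  cfg <- train_config(seed = 33)
  a <- init_network(c(5, 5, 3, 1), cfg)
  b <- init_network(c(5, 5, 3, 1), cfg)
  expect_identical(a$W, b$W)
  expect_identical(vapply(a$W, length, integer(1)), c(25L, 15L, 3L))
  expect_identical(sum(vapply(a$W, length, integer(1))), 43L)
  expect_identical(vapply(a$b, length, integer(1)), c(5L, 3L, 1L))
  expect_true(all(vapply(a$b, function(v) all(v == 0), logical(1))))
  zero <- init_network(c(3, 2, 1), train_config(init_range = 0))
  expect_true(all(vapply(zero$W, function(w) all(w == 0), logical(1))))
  expect_error(init_network(c(3, 2, 2, 2, 1), cfg), "two hidden layers")
  expect_error(init_network(c(3, 2, 2), cfg), "one neuron")
})

test_that("forward pass is tanh-bounded and linear for tiny weights", {
  zero <- init_network(c(4, 3, 1), train_config(init_range = 0))
  expect_equal(nn_forward(zero, matrix(rnorm(40), 10, 4)), rep(0, 10))
  set.seed(5)
  m <- init_network(c(3, 4, 1), train_config(init_range = 0.5, seed = 5))
  X <- matrix(rnorm(60, 0, 5), 20, 3)
  out <- nn_forward(m, X)
  expect_true(all(out > -1 & out < 1))
  # small-weight regime: tanh(z) ~ z, so the net is approximately the
  # composition of its linear maps
  eps <- 1e-3
  tiny <- m
  tiny$W <- lapply(m$W, function(w) w * eps)
  lin <- drop(X %*% (tiny$W[[1]] %*% tiny$W[[2]]))
  expect_equal(nn_forward(tiny, X), lin, tolerance = 1e-4)
  expect_error(nn_forward(m, matrix(0, 2, 5)), "expects 3")
})

test_that("back-propagated gradients match central finite differences", {
  for (seed in 1:4) {
    set.seed(seed)
    arch <- sample(list(c(3, 3, 1), c(2, 4, 1), c(4, 3, 2, 1)), 1)[[1]]
    m <- init_network(arch, train_config(seed = seed))
    X <- matrix(runif(5 * arch[1]), 5, arch[1])
    y <- runif(5, -0.8, 0.8)
    i <- sample(5, 1)
    eta <- 1e-7
    st <- backprop_epoch(m, X, y, eta = eta, alpha = 0, order = i)
    E <- function(model) 0.5 * (y[i] - nn_forward(model, X[i, , drop = FALSE]))^2
    h <- 1e-5
    for (l in seq_along(m$W)) {
      g_bp <- (st$model$W[[l]] - m$W[[l]]) / eta  # equals -dE/dW
      g_fd <- m$W[[l]] * 0
      for (a in seq_len(nrow(g_fd))) for (b in seq_len(ncol(g_fd))) {
        mp <- m; mp$W[[l]][a, b] <- mp$W[[l]][a, b] + h
        mm <- m; mm$W[[l]][a, b] <- mm$W[[l]][a, b] - h
        g_fd[a, b] <- (E(mp) - E(mm)) / (2 * h)
      }
      expect_lt(max(abs(g_bp + g_fd)), 1e-6)
    }
  }
})

test_that("delta-rule degenerate settings behave as stated", {
  set.seed(10)
  m <- init_network(c(3, 3, 1), train_config(seed = 10))
  X <- matrix(runif(12), 4, 3)
  y <- runif(4, -0.5, 0.5)
  frozen <- backprop_epoch(m, X, y, eta = 0, alpha = 0)
  expect_identical(frozen$model$W, m$W)
  # with momentum zero, two consecutive single-pattern updates equal two
  # plain gradient steps (no history term)
  s1 <- backprop_epoch(m, X, y, eta = 0.1, alpha = 0, order = 1)
  s2 <- backprop_epoch(s1$model, X, y, eta = 0.1, alpha = 0, order = 2)
  # momentum buffers hold only the most recent step
  expect_equal(s2$model$W[[1]] - s1$model$W[[1]], s2$model$dW[[1]],
               tolerance = 1e-12)
})

test_that("compiled epoch agrees with the pure-R update loop to 1e-10", {
  set.seed(77)
  for (alpha in c(0, 0.6)) {
    m <- init_network(c(4, 5, 3, 1), train_config(seed = 77))
    X <- matrix(runif(10 * 4), 10, 4)
    y <- runif(10, -0.9, 0.9)
    ord <- sample(10)
    cpp <- backprop_epoch(m, X, y, eta = 0.05, alpha = alpha, order = ord)
    ref <- qsarscreen:::ann_epoch_ref(m, X, y, eta = 0.05, alpha = alpha,
                                      order = ord)
    for (l in seq_along(m$W)) {
      expect_equal(cpp$model$W[[l]], ref$W[[l]], tolerance = 1e-10)
      expect_equal(cpp$model$b[[l]], ref$b[[l]], tolerance = 1e-10)
    }
  }
})

test_that("training converges on a noiseless linear target and is bit-reproducible", {
  spec <- synthetic_spec(120, 3, informative_indices = 1:3,
                         true_coefficients = c(0, 1, -0.5, 0.3),
                         noise_sd = 0, seed = 3)
  ds <- gen_linear_dataset(spec)
  cfg <- train_config(eta = 0.05, alpha = 0.5, max_epochs = 5000,
                      patience = 5000, seed = 5)
  m <- train_ann(ds, arch = c(3, 4, 1), config = cfg)
  expect_lt(tail(m$history$rms_tr, 1), 0.05)
  m2 <- train_ann(ds, arch = c(3, 4, 1), config = cfg)
  expect_identical(m$W, m2$W)
  expect_identical(m$history, m2$history)
})

test_that("early stopping restores the minimum-validation-RMS weights", {
  ds <- nonlinear_benchmark(seed = 4)
  sp <- train_val_split(ds, step = 5)
  m <- train_ann(sp$train, sp$validation, arch = c(8, 6, 1),
                 config = train_config(eta = 0.05, alpha = 0.5,
                                       max_epochs = 400, patience = 60,
                                       seed = 2))
  best <- min(m$history$rms_val)
  expect_equal(m$history$rms_val[m$best_epoch], best, tolerance = 1e-15)
  # re-evaluating the stored weights reproduces the recorded minimum
  Xval <- apply_scaling(m$scaling, sp$validation$descriptors)
  yval <- 2 * (sp$validation$activity - m$activity_params$min) /
    (m$activity_params$max - m$activity_params$min) - 1
  expect_equal(sqrt(mean((yval - nn_forward(m, Xval))^2)), best,
               tolerance = 1e-12)
  # and no recorded epoch did better than the returned weights
  expect_true(all(m$history$rms_val >= best - 1e-15))
})

test_that("prediction is consistent with training history and equivariant under row permutation", {
  ds <- gen_linear_dataset(synthetic_spec(100, 3, informative_indices = 1:2,
                                          true_coefficients = c(1, 0.5, -0.5),
                                          noise_sd = 0.1, seed = 12))
  sp <- train_val_split(ds, step = 5)
  m <- train_ann(sp$train, sp$validation, arch = c(3, 4, 1),
                 config = train_config(eta = 0.02, alpha = 0.01,
                                       max_epochs = 300, patience = 300,
                                       seed = 9))
  pred <- nn_predict(m, sp$train$descriptors)
  scaled_rms <- sqrt(mean((2 * (sp$train$activity - m$activity_params$min) /
                             (m$activity_params$max - m$activity_params$min) -
                           2 * (pred - m$activity_params$min) /
                             (m$activity_params$max - m$activity_params$min))^2))
  expect_equal(scaled_rms, m$history$rms_tr[m$best_epoch], tolerance = 1e-10)
  perm <- sample(nrow(sp$train$descriptors))
  expect_equal(nn_predict(m, sp$train$descriptors[perm, ]), pred[perm])
  # zero-weight model predicts the activity-range midpoint everywhere
  zero <- init_network(c(3, 4, 1), train_config(init_range = 0))
  zero$scaling <- m$scaling
  zero$activity_params <- m$activity_params
  mid <- (m$activity_params$min + m$activity_params$max) / 2
  expect_equal(unname(nn_predict(zero, sp$train$descriptors)),
               rep(mid, nrow(sp$train$descriptors)))
})

test_that("training diverges loudly under an absurd learning rate", {
  # with a linear output neuron nothing bounds the error, so a huge step
  # size must trip the divergence guard rather than fail silently
  ds <- gen_linear_dataset(synthetic_spec(60, 3, informative_indices = 1:2,
                                          true_coefficients = c(0, 1, 1),
                                          noise_sd = 0.1, seed = 2))
  expect_error(train_ann(ds, arch = c(3, 4, 1),
                         config = train_config(eta = 50, alpha = 0.9,
                                               max_epochs = 200,
                                               patience = 200, seed = 1,
                                               linear_output = TRUE)),
               "diverged|non-finite")
})

test_that("input selection recovers planted informative descriptors and is reproducible", {
  spec <- synthetic_spec(200, 35,
                         informative_indices = 1:5,
                         true_coefficients = c(0, 1.2, -1.0, 0.9, 0.8, 1.1),
                         noise_sd = 0.1, seed = 14)
  ds <- gen_linear_dataset(spec)
  sel <- select_inputs(ds$descriptors, ds$activity, n_inputs = 5,
                       probe_epochs = 60, seed = 3)
  expect_setequal(sel, colnames(ds$descriptors)[1:5])
  sel2 <- select_inputs(ds$descriptors, ds$activity, n_inputs = 5,
                        probe_epochs = 60, seed = 3)
  expect_identical(sel, sel2)
  # identity when everything is requested
  all_sel <- select_inputs(ds$descriptors[, 1:5], ds$activity, n_inputs = 5)
  expect_setequal(all_sel, colnames(ds$descriptors)[1:5])
  expect_error(select_inputs(ds$descriptors[, 1:3], ds$activity,
                             n_inputs = 5), "available")
})

test_that("the network beats the best multilinear model on the nonlinear benchmark", {
  ds <- nonlinear_benchmark(seed = 11)
  sp <- train_val_split(ds, step = 5)
  lin <- bmlr_search(sp$train$descriptors, sp$train$activity,
                     k_max = 5)$models$k5
  r2_lin <- cor(predict(lin, sp$validation$descriptors),
                sp$validation$activity)^2
  m <- train_ann(sp$train, sp$validation, arch = c(8, 6, 1),
                 config = ann_benchmark_config())
  r2_ann <- cor(nn_predict(m, sp$validation$descriptors),
                sp$validation$activity)^2
  expect_gte(r2_ann - r2_lin, 0.1)
})
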