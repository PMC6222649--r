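#' Activity-stratified training/validation split
#'
#' Sorts the compounds in ascending order of activity (stable sort; ties
#' keep their original order) and assigns every `step`-th sorted position
#' — ranks `step`, `2*step`, ... — to the validation set; the remainder
#' train the network. Both subsets thereby reflect the distribution of the
#' experimental property over its whole range, which is what the
#' validation-based early stopping in [train_ann()] assumes.
#'
#' @param dataset a `qsar_dataset` (see [gen_linear_dataset()]).
#' @param step every `step`-th sorted compound goes to validation;
#'   conventional values are 3 and 5 (default 5). Other values require
#'   `allow_any_step = TRUE`.
#' @param allow_any_step permit steps outside `{3, 5}`.
#' @return list with `train` and `validation` (both `qsar_dataset`s,
#'   identifiers preserved) and the integer index vectors `train_index`
#'   and `val_index` into the original rows.
#' @export
train_val_split <- function(dataset, step = 5L, allow_any_step = FALSE) {
  stopifnot(inherits(dataset, "qsar_dataset"))
  step <- as.integer(step)
  if (!allow_any_step && !step %in% c(3L, 5L)) {
    stop("step must be 3 or 5 (set allow_any_step = TRUE to override)",
         call. = FALSE)
  }
  n <- nrow(dataset$descriptors)
  if (n < 2L * step) stop(sprintf("need at least %d compounds for step %d",
                                  2L * step, step), call. = FALSE)
  ord <- order(dataset$activity)  # stable
  val_index <- sort(ord[seq(step, n, by = step)])
  train_index <- setdiff(seq_len(n), val_index)
  list(train = subset_dataset(dataset, train_index),
       validation = subset_dataset(dataset, val_index),
       train_index = train_index, val_index = val_index)
}

subset_dataset <- function(dataset, idx) {
  new_qsar_dataset(dataset$descriptors[idx, , drop = FALSE],
                   dataset$activity[idx], dataset$truth)
}

#' Training configuration for the back-propagation network
#'
#' @param eta learning rate (> 0). Published QSAR back-propagation runs of
#'   this style use values around 0.02-0.03.
#' @param alpha momentum coefficient in `[0, 1)`.
#' @param max_epochs maximum number of training epochs.
#' @param patience early stopping: halt after this many consecutive epochs
#'   without the validation RMS improving by more than `min_delta`.
#' @param min_delta minimum decrease of the validation RMS that counts as
#'   an improvement.
#' @param seed integer seed driving weight initialization and the
#'   per-epoch pattern shuffling; training is bit-reproducible given the
#'   seed.
#' @param init_range weights start Uniform(-`init_range`, `init_range`);
#'   biases start at zero.
#' @param linear_output use a linear instead of a tanh output neuron
#'   (targets are normalized to `[-1, 1]`, so tanh is the default).
#' @param shuffle shuffle the pattern order each epoch (recommended for
#'   online updates).
#' @return An object of class `train_config`.
#' @export
train_config <- function(eta = 0.02, alpha = 0.01, max_epochs = 2000L,
                         patience = 50L, min_delta = 1e-5, seed = 1L,
                         init_range = 0.5, linear_output = FALSE,
                         shuffle = TRUE) {
  stopifnot(eta > 0, alpha >= 0, alpha < 1, patience >= 1,
            max_epochs >= 1, init_range >= 0, min_delta >= 0)
  structure(list(eta = eta, alpha = alpha,
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), min_delta = min_delta,
                 seed = as.integer(seed), init_range = init_range,
                 linear_output = isTRUE(linear_output),
                 shuffle = isTRUE(shuffle)),
            class = "train_config")
}

check_architecture <- function(arch, allow_deep = FALSE) {
  arch <- as.integer(arch)
  if (length(arch) < 3L) stop("architecture needs at least one hidden layer",
                              call. = FALSE)
  if (!allow_deep && length(arch) > 4L) {
    stop("at most two hidden layers by default (allow_deep = TRUE to override)",
         call. = FALSE)
  }
  if (arch[length(arch)] != 1L) stop("output layer must have one neuron",
                                     call. = FALSE)
  if (any(arch < 1L)) stop("all layers need at least one neuron", call. = FALSE)
  arch
}

#' Initialize a feed-forward network
#'
#' Builds the layered weight matrices and bias vectors for a fully
#' connected architecture such as `c(5, 5, 3, 1)` (inputs, hidden layers,
#' single output). Weights are drawn Uniform(-`init_range`, `init_range`)
#' from the seeded stream; biases start at zero, as do the momentum
#' buffers.
#'
#' @param arch integer vector of layer sizes; first = number of input
#'   descriptors, last must be 1. One or (by default at most) two hidden
#'   layers.
#' @param config a [train_config()].
#' @param allow_deep permit more than two hidden layers.
#' @return An object of class `neural_model` with weights `W`, biases
#'   `b`, momentum buffers `dW`/`dB`, and slots filled later by
#'   [train_ann()] (scaling, activity normalization, history).
#' @export
init_network <- function(arch, config = train_config(), allow_deep = FALSE) {
  arch <- check_architecture(arch, allow_deep)
  stopifnot(inherits(config, "train_config"))
  L <- length(arch) - 1L
  with_seed(derive_seed(config$seed, 503L), {
    W <- lapply(seq_len(L), function(l) {
      matrix(runif(arch[l] * arch[l + 1], -config$init_range,
                   config$init_range),
             nrow = arch[l], ncol = arch[l + 1])
    })
    b <- lapply(seq_len(L), function(l) numeric(arch[l + 1]))
    dW <- lapply(W, function(w) w * 0)
    dB <- lapply(b, function(v) v * 0)
    structure(list(arch = arch, W = W, b = b, dW = dW, dB = dB,
                   linear_output = config$linear_output,
                   config = config,
                   scaling = NULL, activity_params = NULL,
                   input_names = NULL,
                   history = NULL, best_epoch = NULL),
              class = "neural_model")
  })
}

#' Forward pass of the network
#'
#' Propagates scaled descriptor rows through the network: each layer
#' applies its weights and biases followed by the hyperbolic tangent
#' (the output neuron too, unless the model was configured with a linear
#' output). With a tanh output every prediction lies in (-1, 1), matching
#' the normalized activity scale.
#'
#' @param model a `neural_model`.
#' @param x a single scaled descriptor row or a matrix of rows (columns
#'   must match the input layer size).
#' @return Numeric vector of scaled predictions, one per row.
#' @export
nn_forward <- function(model, x) {
  stopifnot(inherits(model, "neural_model"))
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (ncol(x) != model$arch[1]) {
    stop(sprintf("input has %d columns; network expects %d",
                 ncol(x), model$arch[1]), call. = FALSE)
  }
  A <- x
  L <- length(model$W)
  for (l in seq_len(L)) {
    Z <- sweep(A %*% model$W[[l]], 2, model$b[[l]], "+")
    A <- if (model$linear_output && l == L) Z else tanh(Z)
  }
  drop(A)
}

#' One epoch of online back-propagation (generalized delta rule)
#'
#' Applies the per-pattern update
#' `dw(t) = -eta * dE/dw + alpha * dw(t-1)` with `E = (t - o)^2 / 2` for
#' every training pattern in the given order, modifying the weights after
#' each pattern. Exposed mainly for inspection and testing; [train_ann()]
#' drives it across epochs with shuffling and early stopping.
#'
#' @inheritParams nn_forward
#' @param X scaled descriptor matrix (training patterns).
#' @param y normalized activities in `[-1, 1]`.
#' @param eta,alpha learning rate and momentum (default from the model's
#'   config).
#' @param order integer pattern order (default: as given).
#' @return list with the updated `model` and `rms_tr`, the training RMS
#'   evaluated after the epoch's updates.
#' @export
backprop_epoch <- function(model, X, y, eta = model$config$eta,
                           alpha = model$config$alpha,
                           order = seq_len(nrow(X))) {
  stopifnot(inherits(model, "neural_model"))
  X <- as.matrix(X)
  y <- as.numeric(y)
  stopifnot(nrow(X) == length(y), all(order >= 1L), all(order <= nrow(X)))
  st <- ann_epoch_cpp(model$W, model$b, model$dW, model$dB,
                      X, y, as.integer(order) - 1L,
                      eta, alpha, model$linear_output)
  model$W <- st$W
  model$b <- st$b
  model$dW <- st$dW
  model$dB <- st$dB
  rms <- sqrt(mean((y - nn_forward(model, X))^2))
  list(model = model, rms_tr = rms)
}

# Pure-R reference for the epoch update; kept as the independent second
# route for the update-rule agreement tests.
ann_epoch_ref <- function(model, X, y, eta, alpha, order) {
  W <- model$W; b <- model$b; dW <- model$dW; dB <- model$dB
  L <- length(W)
  for (i in order) {
    a <- vector("list", L + 1L)
    a[[1]] <- as.numeric(X[i, ])
    for (l in seq_len(L)) {
      z <- drop(a[[l]] %*% W[[l]]) + b[[l]]
      a[[l + 1]] <- if (model$linear_output && l == L) z else tanh(z)
    }
    out <- a[[L + 1]][1]
    err <- y[i] - out
    delta <- vector("list", L)
    delta[[L]] <- if (model$linear_output) err else err * (1 - out^2)
    if (L > 1) {
      for (l in seq(L - 1L, 1L)) {
        delta[[l]] <- drop(W[[l + 1]] %*% delta[[l + 1]]) * (1 - a[[l + 1]]^2)
      }
    }
    for (l in seq_len(L)) {
      upd <- eta * outer(a[[l]], delta[[l]]) + alpha * dW[[l]]
      dW[[l]] <- upd
      W[[l]] <- W[[l]] + upd
      updb <- eta * delta[[l]] + alpha * dB[[l]]
      dB[[l]] <- updb
      b[[l]] <- b[[l]] + updb
    }
  }
  model$W <- W; model$b <- b; model$dW <- dW; model$dB <- dB
  model
}

#' Train a back-propagation network with early stopping
#'
#' Scales the training descriptors to `[0, 1]` (min-max, frozen for
#' prediction), normalizes activities to `[-1, 1]`, and runs online
#' back-propagation epochs with per-epoch pattern shuffling. After every
#' epoch the RMS error on the validation set is evaluated; the weights of
#' the epoch with the minimum validation RMS are kept, and training halts
#' early once `patience` consecutive epochs bring no improvement larger
#' than `min_delta` — stopping prematurely when the validation error
#' starts to increase is what protects the network from overfitting.
#'
#' @param train a `qsar_dataset` used for the weight updates.
#' @param validation a `qsar_dataset` monitored for early stopping; if
#'   `NULL`, an activity-stratified split ([train_val_split()]) with
#'   `split_step` is applied to `train` first.
#' @param arch layer sizes, e.g. `c(5, 5, 3, 1)`.
#' @param config a [train_config()].
#' @param split_step passed to [train_val_split()] when `validation` is
#'   `NULL`.
#' @param allow_deep permit more than two hidden layers.
#' @return A fitted `neural_model`: best-epoch weights, frozen
#'   `scaling`/`activity_params`, `history` (data.frame of per-epoch
#'   `rms_tr`/`rms_val`) and `best_epoch`.
#' @export
train_ann <- function(train, validation = NULL, arch, config = train_config(),
                      split_step = 5L, allow_deep = FALSE) {
  stopifnot(inherits(train, "qsar_dataset"))
  if (is.null(validation)) {
    sp <- train_val_split(train, step = split_step)
    train <- sp$train
    validation <- sp$validation
  }
  stopifnot(inherits(validation, "qsar_dataset"))
  arch <- check_architecture(arch, allow_deep)
  if (arch[1] != ncol(train$descriptors)) {
    stop(sprintf("input layer has %d neurons but table has %d descriptors",
                 arch[1], ncol(train$descriptors)), call. = FALSE)
  }

  sc <- scale_descriptors(train$descriptors)
  Xtr <- sc$scaled
  Xval <- apply_scaling(sc$params, validation$descriptors)
  na <- normalize_activity(train$activity)
  ytr <- na$scaled
  yval <- denormalize_inverse(na$params, validation$activity)

  model <- init_network(arch, config)
  model$scaling <- sc$params
  model$activity_params <- na$params
  model$input_names <- colnames(train$descriptors)

  n <- nrow(Xtr)
  rms_of <- function(m, X, y) sqrt(mean((y - nn_forward(m, X))^2))
  initial_rms <- rms_of(model, Xtr, ytr)
  best_val <- Inf
  best_state <- NULL
  best_epoch <- 0L
  stall <- 0L
  hist_tr <- hist_val <- numeric(0)

  for (epoch in seq_len(config$max_epochs)) {
    ord <- if (config$shuffle) {
      with_seed(derive_seed(config$seed, 10000L + epoch), sample.int(n))
    } else {
      seq_len(n)
    }
    st <- ann_epoch_cpp(model$W, model$b, model$dW, model$dB,
                        Xtr, ytr, ord - 1L,
                        config$eta, config$alpha, model$linear_output)
    model$W <- st$W; model$b <- st$b; model$dW <- st$dW; model$dB <- st$dB
    rms_tr <- rms_of(model, Xtr, ytr)
    rms_val <- rms_of(model, Xval, yval)
    hist_tr[epoch] <- rms_tr
    hist_val[epoch] <- rms_val
    if (!is.finite(rms_tr) || rms_tr > 10 * max(initial_rms, 1e-8)) {
      stop(sprintf(
        "training diverged at epoch %d (RMS_tr = %.4g, initial %.4g); lower eta or alpha",
        epoch, rms_tr, initial_rms), call. = FALSE)
    }
    if (rms_val < best_val) {
      improved <- (best_val - rms_val) > config$min_delta
      best_val <- rms_val
      best_state <- list(W = model$W, b = model$b)
      best_epoch <- epoch
      stall <- if (improved) 0L else stall + 1L
    } else {
      stall <- stall + 1L
    }
    if (stall >= config$patience) break
  }

  model$W <- best_state$W
  model$b <- best_state$b
  model$history <- data.frame(epoch = seq_along(hist_tr),
                              rms_tr = hist_tr, rms_val = hist_val)
  model$best_epoch <- best_epoch
  model
}

#' @export
print.neural_model <- function(x, ...) {
  cat(sprintf("neural_model: architecture %s (%s output)\n",
              paste(x$arch, collapse = "-"),
              if (x$linear_output) "linear" else "tanh"))
  if (!is.null(x$history)) {
    i <- x$best_epoch
    cat(sprintf("  trained %d epochs; best epoch %d: RMS_tr = %.4f, RMS_val = %.4f\n",
                nrow(x$history), i, x$history$rms_tr[i], x$history$rms_val[i]))
  } else {
    cat("  untrained\n")
  }
  invisible(x)
}

#' Plot the training history of a fitted network
#'
#' @param x a fitted `neural_model`.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.neural_model <- function(x, ...) {
  if (is.null(x$history)) stop("model has no training history", call. = FALSE)
  graphics::matplot(x$history$epoch,
                    cbind(x$history$rms_tr, x$history$rms_val),
                    type = "l", lty = 1, col = c("black", "red"),
                    xlab = "epoch", ylab = "RMS (scaled units)", ...)
  graphics::abline(v = x$best_epoch, lty = 3)
  graphics::legend("topright", c("training", "validation"),
                   col = c("black", "red"), lty = 1, bty = "n")
  invisible(x)
}

#' Predict logIC50 for new compounds with a trained network
#'
#' Applies the model's frozen training-set scaling to the raw descriptor
#' table, runs the forward pass, and maps the output back from `[-1, 1]`
#' to logIC50 units. Never refits scaling on new data: screening libraries
#' are transformed exactly as the training compounds were.
#'
#' @param model a fitted `neural_model` from [train_ann()].
#' @param table raw descriptor matrix or data.frame containing at least
#'   the model's input descriptors.
#' @return Numeric vector of predicted logIC50 values.
#' @export
nn_predict <- function(model, table) {
  stopifnot(inherits(model, "neural_model"))
  if (is.null(model$scaling)) {
    stop("model carries no scaling parameters; train it with train_ann()",
         call. = FALSE)
  }
  X <- apply_scaling(model$scaling, table)
  if (anyNA(X)) stop("missing descriptor values in prediction table",
                     call. = FALSE)
  denormalize_activity(model$activity_params, nn_forward(model, X))
}

#' Select network input descriptors
#'
#' Ranks all descriptors by single-descriptor R-squared against the
#' activity ([rank_descriptors_by_fit()]), takes the top `n_inputs`, and
#' then performs a deterministic sensitivity sweep: each selected
#' descriptor in turn is tentatively replaced by each non-selected one,
#' and the swap is kept when a short probe training run (a small
#' fixed-architecture network trained for `probe_epochs` epochs from a
#' fixed seed) lowers the validation RMS. The procedure is fully
#' reproducible given the seed.
#'
#' @inheritParams correlation_filter
#' @param n_inputs number of descriptors to select.
#' @param probe_epochs training epochs per probe fit.
#' @param probe_hidden hidden-layer size of the probe network.
#' @param step validation split step for the probe fits.
#' @param seed integer seed for the probe runs.
#' @return Character vector of the selected descriptor names, with the
#'   probe validation RMS as attribute `rms_val`.
#' @export
select_inputs <- function(table, y, n_inputs = 5L, probe_epochs = 150L,
                          probe_hidden = 4L, step = 5L, seed = 1L) {
  table <- as_descriptor_matrix(table)
  y <- check_activity(y, nrow(table))
  n_inputs <- as.integer(n_inputs)
  if (ncol(table) < n_inputs) {
    stop(sprintf("only %d descriptors available, %d requested",
                 ncol(table), n_inputs), call. = FALSE)
  }
  ranking <- rank_descriptors_by_fit(table, y)
  selected <- ranking$descriptor[seq_len(n_inputs)]
  if (ncol(table) == n_inputs) {
    attr(selected, "rms_val") <- NA_real_
    return(selected)
  }
  ds <- new_qsar_dataset(table, y)
  cfg <- train_config(eta = 0.05, alpha = 0.5,
                      max_epochs = as.integer(probe_epochs),
                      patience = as.integer(probe_epochs), seed = seed)
  probe <- function(set) {
    sub <- new_qsar_dataset(ds$descriptors[, set, drop = FALSE], ds$activity)
    m <- train_ann(sub, arch = c(length(set), probe_hidden, 1L),
                   config = cfg, split_step = step)
    min(m$history$rms_val)
  }
  current_rms <- probe(selected)
  for (i in seq_along(selected)) {
    candidates <- setdiff(ranking$descriptor, selected)
    if (length(candidates) == 0L) break
    trial_rms <- vapply(candidates, function(cnd) {
      set <- selected
      set[i] <- cnd
      probe(set)
    }, numeric(1))
    j <- which.min(trial_rms)
    if (trial_rms[j] < current_rms - 1e-9) {
      selected[i] <- candidates[j]
      current_rms <- trial_rms[j]
    }
  }
  attr(selected, "rms_val") <- current_rms
  selected
}
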