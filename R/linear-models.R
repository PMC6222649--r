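#' Fisher statistic from the coefficient of determination
#'
#' For an OLS model with `k` descriptors, an intercept and `n` compounds,
#' `F = (R2 / k) / ((1 - R2) / (n - k - 1))`. Useful for recomputing the
#' F value reported alongside any published regression table from its
#' printed R-squared and dimensions.
#'
#' @param r2 coefficient of determination.
#' @param n number of compounds.
#' @param k number of descriptors (intercept not counted).
#' @return The F statistic.
#' @export
f_statistic <- function(r2, n, k) {
  (r2 / k) / ((1 - r2) / (n - k - 1))
}

#' Ordinary least squares with full QSAR diagnostics
#'
#' Fits `y ~ X` with an intercept (the intercept is always included and is
#' not counted in the descriptor count `k`). Besides the coefficients the
#' fit reports the standard errors, t-statistics, the coefficient of
#' determination, the residual variance `s2 = RSS / (N - k - 1)`, Fisher's
#' statistic `F = (R2/k) / ((1 - R2)/(N - k - 1))` and the leave-one-out
#' cross-validated `R2_cv` — the statistics a QSAR regression table
#' conventionally prints.
#'
#' @param X numeric matrix (or all-numeric data.frame) of descriptors,
#'   rows = compounds; no intercept column.
#' @param y activity vector.
#' @return An object of class `linear_model`: coefficients `B` (named,
#'   intercept first), `SE`, `t_stats`, `R2`, `R2_cv`, `s2`, `F`, `N`,
#'   `k`, `descriptor_names`, plus `fitted`, `residuals` and `leverage`.
#' @export
fit_ols <- function(X, y) {
  X <- as_descriptor_matrix(X)
  y <- check_activity(y, nrow(X))
  N <- nrow(X)
  k <- ncol(X)
  if (N <= k + 1L) {
    stop(sprintf("need N > k + 1 (N = %d, k = %d)", N, k), call. = FALSE)
  }
  Xd <- cbind(`(Intercept)` = 1, X)
  qx <- qr(Xd)
  if (qx$rank < ncol(Xd)) {
    dropped <- colnames(Xd)[qx$pivot[-seq_len(qx$rank)]]
    stop(sprintf("descriptor matrix is rank deficient; collinear column(s): %s",
                 paste(dropped, collapse = ", ")), call. = FALSE)
  }
  B <- qr.coef(qx, y)
  fitted <- drop(Xd %*% B)
  res <- y - fitted
  rss <- sum(res^2)
  sstot <- sum((y - mean(y))^2)
  df <- N - k - 1L
  s2 <- rss / df
  XtXinv <- chol2inv(chol(crossprod(Xd)))
  SE <- sqrt(pmax(diag(XtXinv) * s2, 0))
  names(SE) <- names(B)
  R2 <- 1 - rss / sstot
  Fstat <- f_statistic(R2, N, k)
  h <- rowSums((Xd %*% XtXinv) * Xd)
  r2_cv <- if (any(h >= 1 - 1e-10)) NA_real_ else {
    1 - sum((res / (1 - h))^2) / sstot
  }
  structure(
    list(descriptor_names = colnames(X),
         B = B, SE = SE, t_stats = B / SE,
         R2 = R2, R2_cv = r2_cv, s2 = s2, F = Fstat,
         N = N, k = k,
         fitted = fitted, residuals = res, leverage = h),
    class = "linear_model")
}

#' @export
predict.linear_model <- function(object, newdata, ...) {
  newdata <- as_descriptor_matrix(newdata)
  miss <- setdiff(object$descriptor_names, colnames(newdata))
  if (length(miss) > 0L) {
    stop(sprintf("newdata lacks model descriptor(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  X <- newdata[, object$descriptor_names, drop = FALSE]
  drop(cbind(1, X) %*% object$B)
}

#' @export
print.linear_model <- function(x, digits = 3, ...) {
  cat(sprintf("Multilinear QSAR model: N = %d, k = %d\n", x$N, x$k))
  cat(sprintf("R2 = %.*f, R2_cv = %.*f, s2 = %.*f, F = %.*f\n",
              digits, x$R2, digits, x$R2_cv, digits, x$s2, digits, x$F))
  tab <- data.frame(No = seq_along(x$B) - 1L,
                    B = round(x$B, digits),
                    `Errors B` = round(x$SE, digits),
                    `t-Statistics` = round(x$t_stats, digits),
                    Descriptor = c("Intercept", x$descriptor_names),
                    check.names = FALSE, row.names = NULL)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Leave-one-out cross-validated R-squared
#'
#' Computes the deleted residuals by the hat-matrix shortcut
#' `e_(i) = e_i / (1 - h_ii)` — algebraically identical to refitting the
#' model N times with one compound held out each time — and returns
#' `R2_cv = 1 - PRESS / SS_tot`.
#'
#' @inheritParams fit_ols
#' @return The cross-validated coefficient of determination (a single
#'   number; can be negative for models worse than the mean).
#' @export
loo_r2 <- function(X, y) {
  X <- as_descriptor_matrix(X)
  y <- check_activity(y, nrow(X))
  m <- fit_ols(X, y)
  if (any(m$leverage >= 1 - 1e-10)) {
    stop("a compound has leverage 1; its leave-one-out residual is undefined",
         call. = FALSE)
  }
  press <- sum((m$residuals / (1 - m$leverage))^2)
  1 - press / sum((y - mean(y))^2)
}

# R2 of an OLS fit on a column subset, by fast QR (no diagnostics).
subset_r2 <- function(X, y, idx, sstot) {
  fit <- stats::.lm.fit(cbind(1, X[, idx, drop = FALSE]), y)
  1 - sum(fit$residuals^2) / sstot
}

#' Best multilinear regression (BMLR) stepwise subset search
#'
#' Builds the best k-descriptor OLS equation for each k from 2 to `k_max`
#' by a stepwise beam search over non-collinear descriptor subsets. All
#' admissible descriptor pairs (pairwise `|r| <= max_intercorrelation`)
#' are scored exhaustively at k = 2; for each larger k the `beam_width`
#' best subsets of size k - 1 are each extended by every admissible
#' remaining descriptor. Within a fixed k the best subset is the one with
#' highest R-squared (equivalently highest F: for fixed k and N, F is a
#' monotone function of R-squared).
#'
#' @inheritParams fit_ols
#' @param table descriptor matrix (filters already applied).
#' @param k_max largest descriptor count to search (must be < N - 1).
#' @param max_intercorrelation admissibility cap on the absolute pairwise
#'   Pearson correlation between descriptors in one model.
#' @param beam_width number of size-(k-1) subsets retained for extension.
#' @return An object of class `bmlr_result`: list `models` (one
#'   [fit_ols()] model per k, names `"k2"`, `"k3"`, ...), plus the search
#'   settings.
#' @export
bmlr_search <- function(table, y, k_max = 7L,
                        max_intercorrelation = 0.8,
                        beam_width = 50L) {
  table <- as_descriptor_matrix(table)
  y <- check_activity(y, nrow(table))
  p <- ncol(table)
  N <- nrow(table)
  k_max <- min(as.integer(k_max), p)
  if (k_max >= N - 1L) {
    stop(sprintf("k_max (%d) must be < N - 1 (N = %d)", k_max, N),
         call. = FALSE)
  }
  if (k_max < 2L) stop("k_max must be >= 2", call. = FALSE)
  v <- apply(table, 2, var)
  if (any(v == 0)) stop("zero-variance descriptor present; filter first",
                        call. = FALSE)
  C <- abs(cor(table))
  sstot <- sum((y - mean(y))^2)

  pairs <- which(upper.tri(C) & C <= max_intercorrelation, arr.ind = TRUE)
  if (nrow(pairs) == 0L) {
    stop(sprintf("no admissible descriptor pair at |r| <= %g",
                 max_intercorrelation), call. = FALSE)
  }
  beam <- lapply(seq_len(nrow(pairs)), function(i) as.integer(pairs[i, ]))
  scores <- vapply(beam, function(idx) subset_r2(table, y, idx, sstot),
                   numeric(1))
  ord <- order(-scores)
  best_per_k <- list(`2` = beam[[ord[1]]])
  beam <- beam[head(ord, beam_width)]
  scores <- scores[head(ord, beam_width)]

  k <- 2L
  while (k < k_max) {
    seen <- new.env(hash = TRUE, parent = emptyenv())
    cand <- list()
    cscore <- numeric(0)
    for (b in beam) {
      admissible <- setdiff(which(apply(C[, b, drop = FALSE], 1,
                                        max) <= max_intercorrelation), b)
      for (j in admissible) {
        idx <- sort(c(b, j))
        key <- paste(idx, collapse = ",")
        if (!is.null(seen[[key]])) next
        assign(key, TRUE, envir = seen)
        cand[[length(cand) + 1L]] <- idx
        cscore[length(cand)] <- subset_r2(table, y, idx, sstot)
      }
    }
    if (length(cand) == 0L) break  # no admissible extension; stop growing
    k <- k + 1L
    ord <- order(-cscore)
    best_per_k[[as.character(k)]] <- cand[[ord[1]]]
    beam <- cand[head(ord, beam_width)]
  }

  models <- lapply(best_per_k, function(idx) {
    fit_ols(table[, idx, drop = FALSE], y)
  })
  names(models) <- paste0("k", names(best_per_k))
  structure(list(models = models,
                 k_max = k_max,
                 max_intercorrelation = max_intercorrelation,
                 beam_width = as.integer(beam_width)),
            class = "bmlr_result")
}

#' @export
print.bmlr_result <- function(x, ...) {
  cat(sprintf("BMLR search (k up to %d, |r| cap %.2f, beam %d)\n",
              x$k_max, x$max_intercorrelation, x$beam_width))
  for (nm in names(x$models)) {
    m <- x$models[[nm]]
    cat(sprintf("  %s: R2 = %.3f, F = %.1f [%s]\n", nm, m$R2, m$F,
                paste(m$descriptor_names, collapse = ", ")))
  }
  invisible(x)
}

#' Iterative leverage-based reduction of a training set
#'
#' Removes high-leverage compounds — those whose hat value exceeds
#' `threshold_multiplier * (k + 1) / N` under the current fit — refitting
#' after each pass until no compound exceeds the threshold or the data
#' would fall below `floor_fraction` of its original size. Influential
#' structural outliers otherwise dominate a multilinear fit; trimming them
#' is the standard remedy when a statistically sound linear equation
#' cannot be obtained on the full set.
#'
#' @inheritParams fit_ols
#' @param threshold_multiplier multiplier on the mean leverage
#'   `(k + 1) / N`; `Inf` disables removal.
#' @param floor_fraction never reduce below this fraction of the original
#'   compounds (a warning is raised if the floor stops the iteration).
#' @return list with `descriptors`, `activity` (the reduced data),
#'   `removed_ids` (in removal order) and `passes`.
#' @export
leverage_reduce <- function(X, y, threshold_multiplier = 3,
                            floor_fraction = 0.5) {
  X <- as_descriptor_matrix(X)
  y <- check_activity(y, nrow(X))
  if (is.null(rownames(X))) rownames(X) <- sprintf("R%04d", seq_len(nrow(X)))
  n0 <- nrow(X)
  floor_n <- max(ceiling(floor_fraction * n0), ncol(X) + 2L)
  removed <- character(0)
  passes <- 0L
  repeat {
    m <- fit_ols(X, y)
    cutoff <- threshold_multiplier * (m$k + 1) / m$N
    over <- which(m$leverage > cutoff)
    if (length(over) == 0L) break
    passes <- passes + 1L
    allowed <- nrow(X) - floor_n
    if (allowed <= 0L) {
      warning("leverage reduction stopped at the size floor; high-leverage compounds remain")
      break
    }
    if (length(over) > allowed) {
      over <- over[order(-m$leverage[over])][seq_len(allowed)]
      removed <- c(removed, rownames(X)[over])
      X <- X[-over, , drop = FALSE]
      y <- y[-over]
      warning("leverage reduction stopped at the size floor; high-leverage compounds remain")
      break
    }
    removed <- c(removed, rownames(X)[over])
    X <- X[-over, , drop = FALSE]
    y <- y[-over]
  }
  list(descriptors = X, activity = y, removed_ids = removed, passes = passes)
}

#' Activity-stratified three-way (ABC) split
#'
#' Sorts the compounds in ascending order of activity and deals the sorted
#' positions cyclically into subsets: positions 1, 4, 7, ... form A,
#' positions 2, 5, 8, ... form B, positions 3, 6, 9, ... form C. Ties in
#' the activity are broken by original row index (stable sort). Each
#' subset thus spans the whole activity range, so the held-out folds in
#' [abc_validate()] reflect the property distribution.
#'
#' @param y activity vector.
#' @return A factor of labels `"A"`/`"B"`/`"C"` in the original row order.
#' @export
abc_split <- function(y) {
  y <- check_activity(y)
  ord <- order(y)  # stable: ties keep original order
  lab <- character(length(y))
  lab[ord] <- rep(c("A", "B", "C"), length.out = length(y))
  factor(lab, levels = c("A", "B", "C"))
}

#' ABC external validation of a multilinear model
#'
#' Rebuilds the model (same descriptors, re-optimized coefficients) on
#' each pairwise union of the ABC subsets — AB, BC and CA — and predicts
#' the held-out subset C, A and B respectively. Each fold reports the fit
#' R-squared, the leave-one-out `R2_cv` on the training pair, and the
#' prediction R-squared on the held-out subset; the headline figure is the
#' average of the three prediction R-squared values. An average close to
#' the full-model R-squared indicates a stable, predictive equation.
#'
#' Prediction R-squared is, by default, the squared Pearson correlation
#' between predicted and observed held-out activities; set
#' `r2_pred_method = "press"` for the `1 - PRESS/SS` formulation.
#'
#' @inheritParams bmlr_search
#' @param descriptor_names the descriptors of the model under validation.
#' @param r2_pred_method `"cor"` (default) or `"press"`.
#' @return An object of class `abc_report`: `folds` (data.frame with one
#'   row per fold: train pair, test subset, `r2_fit`, `r2_cv`,
#'   `r2_pred`), `r2_pred_avg`, and the split `labels`.
#' @export
abc_validate <- function(table, y, descriptor_names,
                         r2_pred_method = c("cor", "press")) {
  r2_pred_method <- match.arg(r2_pred_method)
  table <- as_descriptor_matrix(table)
  y <- check_activity(y, nrow(table))
  miss <- setdiff(descriptor_names, colnames(table))
  if (length(miss) > 0L) {
    stop(sprintf("table lacks descriptor(s): %s", paste(miss, collapse = ", ")),
         call. = FALSE)
  }
  X <- table[, descriptor_names, drop = FALSE]
  labels <- abc_split(y)
  folds <- list(c(train = "AB", test = "C"),
                c(train = "BC", test = "A"),
                c(train = "CA", test = "B"))
  rows <- lapply(folds, function(f) {
    tr <- labels %in% strsplit(f[["train"]], "")[[1]]
    te <- labels == f[["test"]]
    if (sum(te) < 3L) {
      stop(sprintf("held-out subset %s has fewer than 3 compounds",
                   f[["test"]]), call. = FALSE)
    }
    m <- fit_ols(X[tr, , drop = FALSE], y[tr])
    pred <- predict(m, X[te, , drop = FALSE])
    obs <- y[te]
    r2_pred <- if (r2_pred_method == "cor") {
      cor(pred, obs)^2
    } else {
      1 - sum((obs - pred)^2) / sum((obs - mean(obs))^2)
    }
    data.frame(train = f[["train"]], test = f[["test"]],
               r2_fit = m$R2, r2_cv = m$R2_cv, r2_pred = r2_pred,
               stringsAsFactors = FALSE)
  })
  folds_df <- do.call(rbind, rows)
  structure(list(folds = folds_df,
                 r2_pred_avg = mean(folds_df$r2_pred),
                 labels = labels,
                 r2_pred_method = r2_pred_method),
            class = "abc_report")
}

#' @export
print.abc_report <- function(x, digits = 3, ...) {
  cat("ABC validation\n")
  for (i in seq_len(nrow(x$folds))) {
    f <- x$folds[i, ]
    cat(sprintf("  (%s,%s): R2 = %.*f  R2_cv = %.*f  R2_pred = %.*f\n",
                f$train, f$test, digits, f$r2_fit, digits, f$r2_cv,
                digits, f$r2_pred))
  }
  cat(sprintf("  average R2_pred = %.*f\n", digits, x$r2_pred_avg))
  invisible(x)
}
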