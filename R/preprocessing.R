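#' Remove descriptors with negligible variance
#'
#' Drops every descriptor whose sample variance (n-1 denominator) is below
#' `threshold`; descriptors with variance at or above the threshold are
#' kept in their original order. Near-constant descriptors carry no
#' information for regression and destabilize scaling, so they are excluded
#' before any other preprocessing step.
#'
#' @param table descriptor matrix or all-numeric data.frame
#'   (rows = compounds).
#' @param threshold minimum sample variance to keep a descriptor.
#' @return The filtered descriptor matrix, with attribute `removed` naming
#'   the dropped descriptors.
#' @export
variance_filter <- function(table, threshold = 1e-4) {
  table <- as_descriptor_matrix(table)
  if (nrow(table) < 2L) stop("need at least 2 compounds to estimate variance",
                             call. = FALSE)
  v <- apply(table, 2, var)
  keep <- v >= threshold
  if (!any(keep)) {
    stop(sprintf("variance filter removed all %d descriptors (threshold %g)",
                 ncol(table), threshold), call. = FALSE)
  }
  out <- table[, keep, drop = FALSE]
  attr(out, "removed") <- colnames(table)[!keep]
  out
}

#' Remove descriptors weakly correlated with the activity
#'
#' Keeps descriptors whose absolute Pearson correlation with the activity
#' exceeds `min_abs_r`. The absolute value is used: a strong negative
#' correlate is as informative as a positive one, and fitted QSAR models
#' routinely carry negative coefficients. Zero-variance descriptors make
#' the correlation undefined and are rejected — run [variance_filter()]
#' first.
#'
#' @inheritParams variance_filter
#' @param y activity vector (logIC50), one value per row of `table`.
#' @param min_abs_r correlation magnitude a descriptor must exceed.
#' @return The filtered descriptor matrix, with attributes `removed` and
#'   `r` (the per-descriptor correlations of the kept columns).
#' @export
correlation_filter <- function(table, y, min_abs_r = 0.2) {
  table <- as_descriptor_matrix(table)
  y <- check_activity(y, nrow(table))
  v <- apply(table, 2, var)
  if (any(v == 0)) {
    stop(sprintf("zero-variance descriptor(s) %s: correlation undefined; apply variance_filter first",
                 paste(colnames(table)[v == 0], collapse = ", ")),
         call. = FALSE)
  }
  r <- drop(cor(table, y))
  keep <- abs(r) > min_abs_r
  if (!any(keep)) {
    stop(sprintf("correlation filter removed all %d descriptors (|r| threshold %g)",
                 ncol(table), min_abs_r), call. = FALSE)
  }
  out <- table[, keep, drop = FALSE]
  attr(out, "removed") <- colnames(table)[!keep]
  attr(out, "r") <- r[keep]
  out
}

#' Scale descriptors and remember the transformation
#'
#' Computes per-descriptor scaling parameters on a training table and
#' applies them. The default `"minmax"` map sends each descriptor to
#' `[0, 1]` via `(x - min) / (max - min)`; `"zscore"` centres to mean 0,
#' sd 1. Parameters are frozen in the returned `scaling_params` object so
#' the identical transformation can be re-applied to screening libraries
#' with [apply_scaling()] — values beyond the training range simply map
#' outside `[0, 1]`, without clipping.
#'
#' @inheritParams variance_filter
#' @param method `"minmax"` (default) or `"zscore"`.
#' @return list with `scaled` (matrix) and `params` (class
#'   `scaling_params`, holding per-descriptor min/max/mean/sd and the
#'   method).
#' @export
scale_descriptors <- function(table, method = c("minmax", "zscore")) {
  method <- match.arg(method)
  table <- as_descriptor_matrix(table)
  mins <- apply(table, 2, min)
  maxs <- apply(table, 2, max)
  if (any(maxs == mins)) {
    stop(sprintf("constant descriptor(s) %s cannot be scaled; apply variance_filter first",
                 paste(colnames(table)[maxs == mins], collapse = ", ")),
         call. = FALSE)
  }
  params <- structure(
    list(method = method,
         min = mins, max = maxs,
         mean = colMeans(table), sd = apply(table, 2, sd)),
    class = "scaling_params")
  list(scaled = apply_scaling(params, table), params = params)
}

#' @rdname scale_descriptors
#' @param params a `scaling_params` object from [scale_descriptors()].
#' @export
apply_scaling <- function(params, table) {
  stopifnot(inherits(params, "scaling_params"))
  table <- as_descriptor_matrix(table, allow_missing = TRUE)
  miss <- setdiff(names(params$min), colnames(table))
  if (length(miss) > 0L) {
    stop(sprintf("table lacks descriptor(s): %s", paste(miss, collapse = ", ")),
         call. = FALSE)
  }
  table <- table[, names(params$min), drop = FALSE]
  if (params$method == "minmax") {
    sweep(sweep(table, 2, params$min, "-"), 2, params$max - params$min, "/")
  } else {
    sweep(sweep(table, 2, params$mean, "-"), 2, params$sd, "/")
  }
}

#' @rdname scale_descriptors
#' @param scaled a matrix produced by [apply_scaling()].
#' @export
invert_scaling <- function(params, scaled) {
  stopifnot(inherits(params, "scaling_params"))
  scaled <- as_descriptor_matrix(scaled, allow_missing = TRUE)
  scaled <- scaled[, names(params$min), drop = FALSE]
  if (params$method == "minmax") {
    sweep(sweep(scaled, 2, params$max - params$min, "*"), 2, params$min, "+")
  } else {
    sweep(sweep(scaled, 2, params$sd, "*"), 2, params$mean, "+")
  }
}

#' Map activities to [-1, 1] and back
#'
#' The network's output neuron is a hyperbolic tangent, so training targets
#' are mapped affinely onto `[-1, 1]`: the minimum activity goes to -1,
#' the maximum to +1, the midpoint to 0. The inverse map is exact.
#'
#' @param y activity vector (logIC50); must not be constant.
#' @return `normalize_activity`: list with `scaled` and `params`
#'   (class `activity_params`, holding min and max).
#' @export
normalize_activity <- function(y) {
  y <- check_activity(y)
  lo <- min(y)
  hi <- max(y)
  if (hi == lo) stop("activity is constant; cannot normalize to [-1, 1]",
                     call. = FALSE)
  params <- structure(list(min = lo, max = hi), class = "activity_params")
  list(scaled = denormalize_inverse(params, y), params = params)
}

denormalize_inverse <- function(params, y) {
  2 * (y - params$min) / (params$max - params$min) - 1
}

#' @rdname normalize_activity
#' @param params an `activity_params` object.
#' @param y_scaled values on the [-1, 1] scale.
#' @export
denormalize_activity <- function(params, y_scaled) {
  stopifnot(inherits(params, "activity_params"))
  (y_scaled + 1) / 2 * (params$max - params$min) + params$min
}

#' Rank descriptors by single-descriptor explanatory power
#'
#' Fits each descriptor alone against the activity and orders descriptors
#' by the resulting coefficient of determination (the squared Pearson
#' correlation, since each fit is univariate with intercept). Ties are
#' broken by descriptor name so the ranking is deterministic.
#'
#' @inheritParams correlation_filter
#' @return data.frame with columns `descriptor` and `r2`, ordered best
#'   first.
#' @export
rank_descriptors_by_fit <- function(table, y) {
  table <- as_descriptor_matrix(table)
  y <- check_activity(y, nrow(table))
  v <- apply(table, 2, var)
  if (any(v == 0)) {
    stop("zero-variance descriptor present; apply variance_filter first",
         call. = FALSE)
  }
  r2 <- drop(cor(table, y))^2
  ord <- order(-r2, colnames(table), method = "radix")
  data.frame(descriptor = colnames(table)[ord], r2 = unname(r2[ord]),
             stringsAsFactors = FALSE)
}
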