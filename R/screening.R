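#' Applicability domain from training descriptor ranges
#'
#' A QSAR model should only be trusted inside the descriptor-space region
#' it was trained on. The domain is defined per descriptor as the training
#' interval `[min_i, max_i]` augmented on both sides by
#' `factor * (max_i - min_i)` (default 30 percent of the range):
#' `lo_i = min_i - factor * range_i`, `hi_i = max_i + factor * range_i`.
#' A compound is inside the domain only if every descriptor falls inside
#' its (closed) interval. A zero-range descriptor collapses to the point
#' plus/minus `epsilon`, with a warning — such columns should normally
#' have been removed by [variance_filter()].
#'
#' @param table training descriptor matrix, restricted to the model's
#'   input descriptors.
#' @param factor fraction of the range added on each side.
#' @param epsilon half-width used for zero-range descriptors.
#' @return An object of class `ad_bounds`: named vectors `lo` and `hi`,
#'   the training `min`/`max`, and the settings.
#' @export
compute_ad <- function(table, factor = 0.3, epsilon = 1e-6) {
  table <- as_descriptor_matrix(table)
  if (nrow(table) == 0L || ncol(table) == 0L) {
    stop("training table is empty", call. = FALSE)
  }
  mins <- apply(table, 2, min)
  maxs <- apply(table, 2, max)
  rng <- maxs - mins
  lo <- mins - factor * rng
  hi <- maxs + factor * rng
  degen <- rng == 0
  if (any(degen)) {
    warning(sprintf("zero-range descriptor(s) %s: bounds collapsed to the point +/- %g",
                    paste(names(lo)[degen], collapse = ", "), epsilon))
    lo[degen] <- mins[degen] - epsilon
    hi[degen] <- maxs[degen] + epsilon
  }
  structure(list(lo = lo, hi = hi, min = mins, max = maxs,
                 factor = factor, epsilon = epsilon),
            class = "ad_bounds")
}

#' @export
print.ad_bounds <- function(x, ...) {
  cat(sprintf("ad_bounds: %d descriptors, +/- %.0f%% of training range\n",
              length(x$lo), 100 * x$factor))
  print(data.frame(lo = x$lo, min = x$min, max = x$max, hi = x$hi))
  invisible(x)
}

#' Test descriptor rows against applicability-domain bounds
#'
#' A row is inside the domain if and only if `lo_i <= D_i <= hi_i` holds
#' simultaneously for every bound descriptor (closed intervals: a value
#' exactly on a bound is inside).
#'
#' @param bounds an [ad_bounds][compute_ad] object.
#' @param table descriptor row (named vector) or matrix covering all bound
#'   descriptors; missing columns or NA values are rejected.
#' @return Logical vector, one flag per row.
#' @export
check_ad <- function(bounds, table) {
  stopifnot(inherits(bounds, "ad_bounds"))
  if (is.null(dim(table))) {
    table <- matrix(table, nrow = 1, dimnames = list(NULL, names(table)))
  }
  table <- as_descriptor_matrix(table, allow_missing = TRUE)
  miss <- setdiff(names(bounds$lo), colnames(table))
  if (length(miss) > 0L) {
    stop(sprintf("row lacks bound descriptor(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  X <- table[, names(bounds$lo), drop = FALSE]
  if (anyNA(X)) {
    stop("missing descriptor values; remove such records (prefilter_library) before the domain check",
         call. = FALSE)
  }
  inside_lo <- sweep(X, 2, bounds$lo, ">=")
  inside_hi <- sweep(X, 2, bounds$hi, "<=")
  unname(rowSums(inside_lo & inside_hi) == ncol(X))
}

subset_library <- function(lib, keep) {
  lib$ids <- lib$ids[keep]
  lib$descriptors <- lib$descriptors[keep, , drop = FALSE]
  lib$mw <- lib$mw[keep]
  lib$purchasable <- lib$purchasable[keep]
  if (!is.null(lib$truth_outside)) lib$truth_outside <- lib$truth_outside[keep]
  lib
}

#' Prefilter a screening library
#'
#' Applies the four standard library-preparation filters, in order:
#' \enumerate{
#'   \item duplicates — records whose identifier already occurred are
#'     dropped (the first occurrence is kept);
#'   \item unclear structural connectivity — represented at this
#'     abstraction level as any record with a missing descriptor value;
#'   \item molecular weight — records with MW strictly above `mw_limit`
#'     (default 600 amu) are dropped; MW exactly at the limit is kept;
#'   \item purchasability — records without purchasable information are
#'     dropped.
#' }
#' A record is counted against the first filter that removes it.
#'
#' @param library a `screening_library` (see [gen_screening_library()]) or
#'   a list with `ids`, `descriptors`, `mw`, `purchasable`.
#' @param mw_limit molecular-weight cutoff in amu.
#' @return list with `library` (the filtered records) and `removal_log`
#'   (counts per filter plus `retained`).
#' @export
prefilter_library <- function(library, mw_limit = 600) {
  stopifnot(is.list(library),
            !is.null(library$ids), !is.null(library$descriptors))
  n0 <- length(library$ids)
  log <- list(duplicates = 0L, missing_descriptors = 0L,
              mw_over_limit = 0L, non_purchasable = 0L)

  dup <- duplicated(library$ids)
  log$duplicates <- sum(dup)
  library <- subset_library(library, !dup)

  has_na <- rowSums(is.na(library$descriptors)) > 0L
  log$missing_descriptors <- sum(has_na)
  library <- subset_library(library, !has_na)

  if (!is.null(library$mw)) {
    heavy <- library$mw > mw_limit
    log$mw_over_limit <- sum(heavy)
    library <- subset_library(library, !heavy)
  }
  if (!is.null(library$purchasable)) {
    np <- !library$purchasable | is.na(library$purchasable)
    log$non_purchasable <- sum(np)
    library <- subset_library(library, !np)
  }
  log$retained <- length(library$ids)
  if (log$retained == 0L) warning("all records removed by the prefilters")
  list(library = library, removal_log = log)
}

#' Consensus ANN + MLR screening of a compound library
#'
#' Predicts logIC50 for every record with both the neural and the
#' multilinear model, averages the two predictions, flags applicability-
#' domain membership, and ranks the in-domain records in ascending order
#' of the average prediction — a lower predicted logIC50 means a more
#' potent compound, so rank 1 is the best candidate. Out-of-domain
#' records keep their predictions but carry no rank. Ties are broken by
#' compound identifier.
#'
#' @param library a prefiltered `screening_library` (no missing
#'   descriptor values; see [prefilter_library()]).
#' @param neural_model a fitted `neural_model` ([train_ann()]).
#' @param linear_model a `linear_model` ([fit_ols()]).
#' @param bounds an [ad_bounds][compute_ad] object on the union of both
#'   models' descriptors.
#' @return A data.frame (class `screening_result`) with columns
#'   `compound_id`, `pred_ann`, `pred_mlr`, `pred_avg`, `in_ad`, `rank`,
#'   ordered ranked records first.
#' @export
consensus_screen <- function(library, neural_model, linear_model, bounds) {
  stopifnot(inherits(neural_model, "neural_model"),
            inherits(linear_model, "linear_model"),
            inherits(bounds, "ad_bounds"))
  D <- as_descriptor_matrix(library$descriptors, allow_missing = TRUE)
  needed <- unique(c(names(neural_model$scaling$min),
                     linear_model$descriptor_names, names(bounds$lo)))
  miss <- setdiff(needed, colnames(D))
  if (length(miss) > 0L) {
    stop(sprintf("library lacks model descriptor(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  if (anyNA(D[, needed, drop = FALSE])) {
    stop("library contains missing descriptor values; run prefilter_library() first",
         call. = FALSE)
  }
  pred_ann <- nn_predict(neural_model, D)
  pred_mlr <- predict(linear_model, D)
  pred_avg <- (pred_ann + pred_mlr) / 2
  in_ad <- check_ad(bounds, D)
  res <- data.frame(compound_id = library$ids,
                    pred_ann = pred_ann, pred_mlr = pred_mlr,
                    pred_avg = pred_avg, in_ad = in_ad,
                    rank = NA_integer_,
                    stringsAsFactors = FALSE, row.names = NULL)
  inside <- which(res$in_ad)
  ord <- inside[order(res$pred_avg[inside], res$compound_id[inside],
                      method = "radix")]
  res$rank[ord] <- seq_along(ord)
  res <- res[order(!res$in_ad, res$rank), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("screening_result", "data.frame")
  res
}

#' Shortlist the top-ranked screening candidates
#'
#' Takes the first `min(n, available)` ranked (in-domain) records of a
#' screening result. When `fraction` is given, a second cut keeps only
#' the top `fraction` of that shortlist — the conventional hand-off to
#' structure-based follow-up (e.g. a 0.4 cut of a top-100 shortlist
#' passes 40 compounds to docking).
#'
#' @param results a `screening_result` from [consensus_screen()].
#' @param n shortlist size.
#' @param fraction optional proportion for the second cut.
#' @return The shortlisted rows, a prefix of the ranking.
#' @export
top_selection <- function(results, n = 100L, fraction = NULL) {
  stopifnot(inherits(results, "data.frame"), !is.null(results$rank))
  ranked <- results[!is.na(results$rank), , drop = FALSE]
  ranked <- ranked[order(ranked$rank), , drop = FALSE]
  out <- head(ranked, n)
  if (!is.null(fraction)) {
    stopifnot(fraction > 0, fraction <= 1)
    out <- head(out, max(1L, round(fraction * nrow(out))))
  }
  rownames(out) <- NULL
  out
}
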