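#' Specification for a synthetic QSAR dataset
#'
#' Describes a descriptor table and activity vector with known ground truth:
#' which descriptors carry signal, their linear coefficients, the noise
#' level, optional collinear descriptor blocks and near-constant descriptor
#' columns. Generators consume the spec; fitted-model tests read the truth
#' back from the generated dataset.
#'
#' Descriptor marginals are Uniform(`descriptor_range[1]`,
#' `descriptor_range[2]`), defaulting to Uniform(0, 10); real molecular
#' descriptors carry no canonical scale, so an overridable flat marginal is
#' used. Collinearity is induced through a Gaussian copula (see
#' [gen_linear_dataset()]).
#'
#' @param n_compounds number of compounds (rows).
#' @param n_descriptors number of descriptor columns.
#' @param informative_indices columns of the descriptor matrix that enter
#'   the linear response.
#' @param true_coefficients numeric vector `c(intercept, b_1, ..., b_m)`
#'   with one slope per informative index.
#' @param noise_sd standard deviation of the additive Gaussian noise, in
#'   logIC50 units. Must be non-negative.
#' @param collinear_blocks list of blocks, each `list(indices =, r =)`:
#'   the listed descriptor columns are generated with pairwise Pearson
#'   correlation close to `r`.
#' @param near_constant_indices columns replaced by near-constant values
#'   (sample variance below 1e-4), exercising the variance filter.
#' @param seed integer seed; a fixed seed makes the output bit-identical
#'   across runs.
#' @param descriptor_range length-2 numeric, the uniform marginal range.
#'
#' @return An object of class `synthetic_spec`.
#' @seealso [gen_linear_dataset()], [gen_nonlinear_dataset()]
#' @export
synthetic_spec <- function(n_compounds,
                           n_descriptors,
                           informative_indices = integer(),
                           true_coefficients = 0,
                           noise_sd = 0,
                           collinear_blocks = list(),
                           near_constant_indices = integer(),
                           seed = 1L,
                           descriptor_range = c(0, 10)) {
  n_compounds <- as.integer(n_compounds)
  n_descriptors <- as.integer(n_descriptors)
  informative_indices <- as.integer(informative_indices)
  stopifnot(n_compounds > 0L, n_descriptors > 0L)
  bad <- informative_indices[informative_indices < 1L |
                             informative_indices > n_descriptors]
  if (length(bad) > 0L) {
    stop(sprintf("informative index out of range: %s (valid range 1..%d)",
                 paste(bad, collapse = ", "), n_descriptors), call. = FALSE)
  }
  if (anyDuplicated(informative_indices)) {
    stop("informative_indices must be unique", call. = FALSE)
  }
  if (length(true_coefficients) != length(informative_indices) + 1L) {
    stop(sprintf(
      "true_coefficients must have length %d (intercept + one slope per informative index)",
      length(informative_indices) + 1L), call. = FALSE)
  }
  if (!is.numeric(noise_sd) || length(noise_sd) != 1L || noise_sd < 0) {
    stop("noise_sd must be a single non-negative number", call. = FALSE)
  }
  for (blk in collinear_blocks) {
    idx <- as.integer(blk$indices)
    if (length(idx) < 2L || any(idx < 1L) || any(idx > n_descriptors)) {
      stop("each collinear block needs >= 2 in-range descriptor indices",
           call. = FALSE)
    }
    if (!is.numeric(blk$r) || abs(blk$r) >= 1) {
      stop("collinear block target correlation must lie in (-1, 1)",
           call. = FALSE)
    }
  }
  near_constant_indices <- as.integer(near_constant_indices)
  if (any(near_constant_indices < 1L | near_constant_indices > n_descriptors)) {
    stop("near_constant index out of range", call. = FALSE)
  }
  stopifnot(length(descriptor_range) == 2L,
            descriptor_range[2] > descriptor_range[1])
  structure(
    list(n_compounds = n_compounds,
         n_descriptors = n_descriptors,
         informative_indices = informative_indices,
         true_coefficients = as.numeric(true_coefficients),
         noise_sd = as.numeric(noise_sd),
         collinear_blocks = collinear_blocks,
         near_constant_indices = near_constant_indices,
         seed = as.integer(seed),
         descriptor_range = as.numeric(descriptor_range)),
    class = "synthetic_spec")
}

# Draw the descriptor matrix for a spec: uniform marginals, Gaussian-copula
# collinear blocks, near-constant columns overwritten last.
draw_descriptors <- function(spec) {
  n <- spec$n_compounds
  p <- spec$n_descriptors
  lo <- spec$descriptor_range[1]
  hi <- spec$descriptor_range[2]
  D <- matrix(runif(n * p, lo, hi), nrow = n, ncol = p,
              dimnames = list(sprintf("C%04d", seq_len(n)),
                              sprintf("D%03d", seq_len(p))))
  for (blk in spec$collinear_blocks) {
    idx <- as.integer(blk$indices)
    m <- length(idx)
    # Uniforms built from a Gaussian copula have Pearson correlation
    # (6/pi)*asin(r_latent/2); invert so the block hits the target r.
    r_latent <- 2 * sin(pi * blk$r / 6)
    sigma <- matrix(r_latent, m, m)
    diag(sigma) <- 1
    ch <- tryCatch(chol(sigma), error = function(e) {
      stop(sprintf("collinear block correlation %.3f is not attainable for %d descriptors",
                   blk$r, m), call. = FALSE)
    })
    Z <- matrix(rnorm(n * m), n, m) %*% ch
    D[, idx] <- lo + (hi - lo) * pnorm(Z)
  }
  mid <- (lo + hi) / 2
  for (j in spec$near_constant_indices) {
    D[, j] <- mid + rnorm(n, 0, 1e-3)  # variance ~1e-6, below the 1e-4 filter
  }
  D
}

#' Generate a dataset with a known linear descriptor-activity relationship
#'
#' Draws a descriptor matrix per the spec and computes
#' `activity_i = b0 + sum_j b_j D_ij + eps_i` with
#' `eps ~ Normal(0, noise_sd^2)` over the informative columns only.
#' Collinear blocks reach their target pairwise correlation to within about
#' 0.05 for n >= 100 (Gaussian-copula construction). With `noise_sd = 0`
#' the activity is an exact linear function of the informative descriptors,
#' so an OLS fit on those columns recovers `true_coefficients` exactly and
#' has R-squared 1.
#'
#' @param spec a [synthetic_spec()].
#' @return An object of class `qsar_dataset`: a list with `descriptors`
#'   (numeric matrix, rows = compounds), `activity` (numeric vector,
#'   logIC50 units) and `truth` (the spec, carried for assertions).
#' @export
gen_linear_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(derive_seed(spec$seed, 101L), {
    D <- draw_descriptors(spec)
    b <- spec$true_coefficients
    y <- rep(b[1], spec$n_compounds)
    if (length(spec$informative_indices) > 0L) {
      y <- y + drop(D[, spec$informative_indices, drop = FALSE] %*% b[-1])
    }
    if (spec$noise_sd > 0) {
      y <- y + rnorm(spec$n_compounds, 0, spec$noise_sd)
    }
    new_qsar_dataset(D, y, spec)
  })
}

#' The fixed nonlinear response surface used by [gen_nonlinear_dataset()]
#'
#' For a descriptor matrix `D` (at least 4 columns, nominal range 0..10):
#' \deqn{f(D) = 3\tanh((D_1 - 5)/1.5) + 0.2 (D_2 - 5)(D_3 - 5) + 0.2 D_4}
#' A saturating term in the first descriptor, a product (interaction) term
#' in the second and third, and a weak linear term in the fourth. The
#' saturation scale and interaction weight are chosen so that a
#' multilinear fit can explain only about two thirds of the response
#' variance while the surface stays smooth and learnable. At the all-zero
#' row the value is `5 - 3*tanh(10/3)` (approximately 2.0148357).
#'
#' @param D numeric matrix with at least 4 columns.
#' @return Numeric vector of responses, one per row.
#' @export
nonlinear_response <- function(D) {
  D <- as_descriptor_matrix(D)
  if (ncol(D) < 4L) stop("nonlinear response needs at least 4 descriptors",
                         call. = FALSE)
  unname(3 * tanh((D[, 1] - 5) / 1.5) +
           0.2 * (D[, 2] - 5) * (D[, 3] - 5) +
           0.2 * D[, 4])
}

#' Generate a dataset with a smooth nonlinear descriptor-activity surface
#'
#' Identical descriptor generation to [gen_linear_dataset()], but the
#' activity is [nonlinear_response()] of the first four descriptors plus
#' Gaussian noise. The surface contains an interaction and a saturating
#' term that a multilinear model cannot represent, so it separates linear
#' from neural fits by construction. `informative_indices` and
#' `true_coefficients` in the spec are ignored (the response is fixed).
#'
#' @inheritParams gen_linear_dataset
#' @return A `qsar_dataset`; `truth$response` is set to `"nonlinear"`.
#' @export
gen_nonlinear_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (spec$n_descriptors < 4L) {
    stop("gen_nonlinear_dataset needs n_descriptors >= 4", call. = FALSE)
  }
  with_seed(derive_seed(spec$seed, 211L), {
    D <- draw_descriptors(spec)
    y <- nonlinear_response(D)
    if (spec$noise_sd > 0) {
      y <- y + rnorm(spec$n_compounds, 0, spec$noise_sd)
    }
    spec$response <- "nonlinear"
    new_qsar_dataset(D, y, spec)
  })
}

new_qsar_dataset <- function(descriptors, activity, truth = NULL) {
  descriptors <- as_descriptor_matrix(descriptors)
  activity <- check_activity(activity, nrow(descriptors))
  names(activity) <- rownames(descriptors)
  structure(list(descriptors = descriptors, activity = activity,
                 truth = truth),
            class = "qsar_dataset")
}

#' @export
print.qsar_dataset <- function(x, ...) {
  cat(sprintf("qsar_dataset: %d compounds x %d descriptors\n",
              nrow(x$descriptors), ncol(x$descriptors)))
  cat(sprintf("  activity (logIC50): range [%.3f, %.3f]\n",
              min(x$activity), max(x$activity)))
  if (!is.null(x$truth)) cat("  ground truth attached\n")
  invisible(x)
}

#' Noise level giving a target population R-squared for a linear spec
#'
#' For independent Uniform(a, b) descriptors, the population signal
#' variance is `sum(b_j^2) * (b - a)^2 / 12`; the noise standard deviation
#' that yields population R-squared `r2` is
#' `sqrt(var_signal * (1 - r2) / r2)`.
#'
#' @param true_coefficients `c(intercept, slopes...)` as in
#'   [synthetic_spec()].
#' @param r2 target population coefficient of determination in (0, 1).
#' @param descriptor_range the uniform marginal range.
#' @return The noise standard deviation (logIC50 units).
#' @export
noise_sd_for_r2 <- function(true_coefficients, r2, descriptor_range = c(0, 10)) {
  stopifnot(r2 > 0, r2 < 1)
  slopes <- true_coefficients[-1]
  var_signal <- sum(slopes^2) * diff(descriptor_range)^2 / 12
  sqrt(var_signal * (1 - r2) / r2)
}

#' Generate a screening library with known applicability-domain truth
#'
#' Emulates a prepared natural-product screening library: descriptor
#' records drawn inside given applicability-domain bounds, with an exact
#' number `round(n * frac_outside)` of records pushed outside the bounds on
#' at least one descriptor, plus planted violations of the standard library
#' prefilters — duplicate identifiers, records with a missing descriptor
#' value (standing in for unclear structural connectivity), molecular
#' weight above 600 amu, and records without purchasability information.
#'
#' The planted prefilter-violation row sets are disjoint from each other
#' and from the out-of-domain rows, so every planted count can be asserted
#' independently. Records with a missing descriptor have `truth_outside`
#' set to `NA` (domain membership is undefined for them).
#'
#' @param n number of records.
#' @param ad_bounds an [ad_bounds] object from [compute_ad()].
#' @param frac_outside fraction of records outside the domain, in `[0, 1]`.
#' @param seed integer seed.
#' @param n_mw_violations,n_duplicates,n_nonpurchasable,n_missing counts of
#'   planted prefilter violations; defaults scale mildly with `n`.
#' @return An object of class `screening_library`: list with `ids`,
#'   `descriptors` (matrix, may contain NA in planted rows), `mw`,
#'   `purchasable` (logical), `truth_outside` (logical, NA where
#'   descriptors are missing) and `planted` (the violation counts).
#' @export
gen_screening_library <- function(n, ad_bounds, frac_outside = 0, seed = 1L,
                                  n_mw_violations = max(1L, round(0.03 * n)),
                                  n_duplicates = max(1L, round(0.02 * n)),
                                  n_nonpurchasable = max(1L, round(0.02 * n)),
                                  n_missing = max(1L, round(0.01 * n))) {
  stopifnot(inherits(ad_bounds, "ad_bounds"))
  n <- as.integer(n)
  if (length(ad_bounds$lo) == 0L) stop("ad_bounds is empty", call. = FALSE)
  if (!is.numeric(frac_outside) || frac_outside < 0 || frac_outside > 1) {
    stop("frac_outside must lie in [0, 1]", call. = FALSE)
  }
  n_out <- as.integer(round(n * frac_outside))
  n_special <- n_mw_violations + n_duplicates + n_nonpurchasable + n_missing
  if (n_out + n_special > n) {
    stop("planted violations plus out-of-domain records exceed n", call. = FALSE)
  }
  lo <- ad_bounds$lo
  hi <- ad_bounds$hi
  p <- length(lo)
  with_seed(derive_seed(seed, 307L), {
    D <- vapply(seq_len(p), function(j) runif(n, lo[j], hi[j]),
                numeric(n))
    dim(D) <- c(n, p)
    colnames(D) <- names(lo)
    ids <- sprintf("Z%06d", sample.int(10L * n, n))
    rownames(D) <- ids
    # disjoint planted row sets, sliced from one draw by cumulative offset
    pick <- sample.int(n, n_out + n_special)
    slice <- function(from, len) {
      if (len > 0L) pick[from:(from + len - 1L)] else integer(0)
    }
    rows_out <- slice(1L, n_out)
    rows_mw  <- slice(n_out + 1L, n_mw_violations)
    rows_dup <- slice(n_out + n_mw_violations + 1L, n_duplicates)
    rows_np  <- slice(n_out + n_mw_violations + n_duplicates + 1L,
                      n_nonpurchasable)
    rows_na  <- slice(n_out + n_mw_violations + n_duplicates +
                        n_nonpurchasable + 1L, n_missing)
    for (i in rows_out) {
      j <- sample.int(p, 1L)
      span <- max(hi[j] - lo[j], 1)
      off <- runif(1, 0.05, 0.5) * span
      D[i, j] <- if (runif(1) < 0.5) lo[j] - off else hi[j] + off
    }
    mw <- runif(n, 150, 595)
    mw[rows_mw] <- runif(n_mw_violations, 601, 900)
    purchasable <- rep(TRUE, n)
    purchasable[rows_np] <- FALSE
    # duplicate ids point at non-planted originals
    originals <- setdiff(seq_len(n), pick)
    ids[rows_dup] <- ids[originals[sample.int(length(originals),
                                              n_duplicates)]]
    rownames(D) <- NULL
    truth_outside <- rep(FALSE, n)
    truth_outside[rows_out] <- TRUE
    for (i in rows_na) {
      D[i, sample.int(p, 1L)] <- NA_real_
    }
    truth_outside[rows_na] <- NA
    structure(
      list(ids = ids, descriptors = D, mw = mw, purchasable = purchasable,
           truth_outside = truth_outside,
           planted = list(n_outside = as.integer(n_out),
                          n_mw = as.integer(n_mw_violations),
                          n_duplicates = as.integer(n_duplicates),
                          n_nonpurchasable = as.integer(n_nonpurchasable),
                          n_missing = as.integer(n_missing)),
           seed = as.integer(seed)),
      class = "screening_library")
  })
}

#' @export
print.screening_library <- function(x, ...) {
  cat(sprintf("screening_library: %d records x %d descriptors\n",
              length(x$ids), ncol(x$descriptors)))
  cat(sprintf("  planted: %d out-of-domain, %d MW>600, %d duplicate ids, %d non-purchasable, %d with missing descriptors\n",
              x$planted$n_outside, x$planted$n_mw, x$planted$n_duplicates,
              x$planted$n_nonpurchasable, x$planted$n_missing))
  invisible(x)
}
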