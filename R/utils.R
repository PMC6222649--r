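# Internal helpers: seeded evaluation, deterministic sub-seeds, input checks.

# Evaluate `code` under `set.seed(seed)`, restoring the caller's RNG state
# afterwards so library calls never perturb a user's random stream.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv(), inherits = FALSE)
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# One global seed drives everything; per-operation (and per-epoch) streams
# are derived deterministically and stay below 2^31 - 1.
derive_seed <- function(seed, offset) {
  s <- (abs(as.numeric(seed)) %% 1000003) * 1201 + (abs(as.numeric(offset)) %% 65521) * 17
  as.integer(s %% 2147483647) + 1L
}

# Coerce a descriptor table (matrix or data.frame of numeric columns) to a
# numeric matrix with unique column names and no missing values.
as_descriptor_matrix <- function(table, allow_missing = FALSE) {
  if (is.data.frame(table)) {
    if (!all(vapply(table, is.numeric, logical(1)))) {
      stop("descriptor table must contain only numeric columns", call. = FALSE)
    }
    table <- as.matrix(table)
  }
  if (!is.matrix(table) || !is.numeric(table)) {
    stop("descriptor table must be a numeric matrix or data.frame", call. = FALSE)
  }
  if (is.null(colnames(table))) {
    colnames(table) <- sprintf("D%03d", seq_len(ncol(table)))
  }
  if (anyDuplicated(colnames(table))) {
    stop("descriptor names must be unique", call. = FALSE)
  }
  if (!allow_missing && anyNA(table)) {
    stop("descriptor table must not contain missing values", call. = FALSE)
  }
  table
}

check_activity <- function(y, n_rows = NULL) {
  if (!is.numeric(y) || length(y) == 0L) {
    stop("activity must be a non-empty numeric vector", call. = FALSE)
  }
  if (anyNA(y) || any(!is.finite(y))) {
    stop("activity values must be finite", call. = FALSE)
  }
  if (!is.null(n_rows) && length(y) != n_rows) {
    stop(sprintf("activity length (%d) does not match row count (%d)",
                 length(y), n_rows), call. = FALSE)
  }
  as.numeric(y)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
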