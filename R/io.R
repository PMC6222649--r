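# CSV and JSON plumbing: datasets, screening libraries, fitted models,
# scaling parameters, applicability-domain bounds, validation reports.

stop_io <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("qsar_io_error", "error", "condition")))
}

stop_validation <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("qsar_validation_error", "error", "condition")))
}

#' Read and write labelled QSAR datasets as CSV
#'
#' The on-disk layout is one header row, first column `compound_id`,
#' then one column per descriptor, last column `activity` (logIC50).
#' `write_dataset_csv()` optionally writes a JSON sidecar carrying the
#' generating [synthetic_spec()] so ground truth travels with the file.
#'
#' @param dataset a `qsar_dataset`.
#' @param path CSV file path.
#' @param truth_path optional path for the JSON truth sidecar.
#' @return `read_dataset_csv()` returns a `qsar_dataset` (with `truth`
#'   re-attached when the sidecar exists next to the file).
#' @export
write_dataset_csv <- function(dataset, path, truth_path = NULL) {
  stopifnot(inherits(dataset, "qsar_dataset"))
  df <- data.frame(compound_id = rownames(dataset$descriptors),
                   dataset$descriptors,
                   activity = unname(dataset$activity),
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.csv(df, path, row.names = FALSE)
  if (!is.null(truth_path) && !is.null(dataset$truth)) {
    truth <- dataset$truth
    class(truth) <- NULL
    jsonlite::write_json(truth, truth_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname write_dataset_csv
#' @export
read_dataset_csv <- function(path) {
  if (!file.exists(path)) stop_io("dataset file not found: %s", path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!identical(colnames(df)[1], "compound_id")) {
    stop_validation("%s: first column must be 'compound_id' (header row mandatory)",
                    path)
  }
  if (!"activity" %in% colnames(df)) {
    stop_validation("%s: missing 'activity' column", path)
  }
  desc_cols <- setdiff(colnames(df), c("compound_id", "activity"))
  for (cn in desc_cols) {
    if (!is.numeric(df[[cn]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(df[[cn]]))))[1]
      stop_validation("%s: non-numeric cell in column '%s' at line %d",
                      path, cn, bad + 1L)  # +1 for the header line
    }
  }
  if (!is.numeric(df$activity)) {
    bad <- which(is.na(suppressWarnings(as.numeric(df$activity))))[1]
    stop_validation("%s: non-numeric activity at line %d", path, bad + 1L)
  }
  D <- as.matrix(df[, desc_cols, drop = FALSE])
  rownames(D) <- df$compound_id
  truth <- NULL
  sidecar <- paste0(tools::file_path_sans_ext(path), "_truth.json")
  if (file.exists(sidecar)) {
    truth <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  }
  new_qsar_dataset(D, df$activity, truth)
}

#' Read and write screening libraries as CSV
#'
#' Layout: `compound_id`, descriptor columns, then optional `MW` and
#' `purchasable` columns. Missing descriptor cells are preserved (they
#' mark records with unclear structural connectivity and are removed by
#' [prefilter_library()]).
#'
#' @param library a `screening_library`.
#' @param path CSV file path.
#' @export
write_library_csv <- function(library, path) {
  df <- data.frame(compound_id = library$ids,
                   library$descriptors,
                   check.names = FALSE, stringsAsFactors = FALSE)
  if (!is.null(library$mw)) df$MW <- library$mw
  if (!is.null(library$purchasable)) df$purchasable <- library$purchasable
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_library_csv
#' @export
read_library_csv <- function(path) {
  if (!file.exists(path)) stop_io("library file not found: %s", path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!identical(colnames(df)[1], "compound_id")) {
    stop_validation("%s: first column must be 'compound_id'", path)
  }
  aux <- intersect(c("MW", "purchasable"), colnames(df))
  desc_cols <- setdiff(colnames(df), c("compound_id", aux))
  D <- as.matrix(df[, desc_cols, drop = FALSE])
  if (!is.numeric(D)) stop_validation("%s: non-numeric descriptor cells", path)
  structure(list(ids = df$compound_id, descriptors = D,
                 mw = if ("MW" %in% aux) df$MW else NULL,
                 purchasable = if ("purchasable" %in% aux) {
                   as.logical(df$purchasable)
                 } else NULL,
                 truth_outside = NULL, planted = NULL),
            class = "screening_library")
}

# --- model serialization ----------------------------------------------------

scaling_to_list <- function(p) {
  list(method = p$method, descriptors = names(p$min),
       min = unname(p$min), max = unname(p$max),
       mean = unname(p$mean), sd = unname(p$sd))
}

scaling_from_list <- function(l) {
  nm <- unlist(l$descriptors)
  structure(list(method = l$method,
                 min = setNames(unlist(l$min), nm),
                 max = setNames(unlist(l$max), nm),
                 mean = setNames(unlist(l$mean), nm),
                 sd = setNames(unlist(l$sd), nm)),
            class = "scaling_params")
}

model_to_list <- function(x) {
  if (inherits(x, "linear_model")) {
    list(type = "linear_model",
         descriptor_names = x$descriptor_names,
         B = unname(x$B), SE = unname(x$SE), t_stats = unname(x$t_stats),
         R2 = x$R2, R2_cv = x$R2_cv, s2 = x$s2, F = x$F,
         N = x$N, k = x$k)
  } else if (inherits(x, "neural_model")) {
    list(type = "neural_model",
         arch = x$arch,
         W = lapply(x$W, function(m) as.data.frame(m)),
         b = x$b,
         linear_output = x$linear_output,
         input_names = x$input_names,
         scaling = if (!is.null(x$scaling)) scaling_to_list(x$scaling) else NULL,
         activity_params = if (!is.null(x$activity_params)) {
           unclass(x$activity_params)
         } else NULL,
         history = x$history,
         best_epoch = x$best_epoch)
  } else if (inherits(x, "ad_bounds")) {
    list(type = "ad_bounds", descriptors = names(x$lo),
         lo = unname(x$lo), hi = unname(x$hi),
         min = unname(x$min), max = unname(x$max),
         factor = x$factor, epsilon = x$epsilon)
  } else if (inherits(x, "scaling_params")) {
    c(list(type = "scaling_params"), scaling_to_list(x))
  } else if (inherits(x, "abc_report")) {
    list(type = "abc_report", folds = x$folds,
         r2_pred_avg = x$r2_pred_avg,
         labels = as.character(x$labels),
         r2_pred_method = x$r2_pred_method)
  } else {
    stop("unsupported model class: ", paste(class(x), collapse = "/"),
         call. = FALSE)
  }
}

list_to_model <- function(lst) {
  switch(lst$type,
    linear_model = {
      B <- setNames(lst$B, c("(Intercept)", lst$descriptor_names))
      structure(list(descriptor_names = lst$descriptor_names,
                     B = B,
                     SE = setNames(lst$SE, names(B)),
                     t_stats = setNames(lst$t_stats, names(B)),
                     R2 = lst$R2, R2_cv = lst$R2_cv, s2 = lst$s2, F = lst$F,
                     N = lst$N, k = lst$k),
                class = "linear_model")
    },
    neural_model = {
      W <- lapply(lst$W, function(d) unname(as.matrix(as.data.frame(d))))
      sc <- if (!is.null(lst$scaling)) scaling_from_list(lst$scaling) else NULL
      ap <- if (!is.null(lst$activity_params)) {
        structure(list(min = lst$activity_params$min,
                       max = lst$activity_params$max),
                  class = "activity_params")
      } else NULL
      structure(list(arch = as.integer(unlist(lst$arch)),
                     W = W,
                     b = lapply(lst$b, unlist),
                     dW = lapply(W, function(m) m * 0),
                     dB = lapply(lst$b, function(v) unlist(v) * 0),
                     linear_output = isTRUE(lst$linear_output),
                     config = NULL,
                     scaling = sc, activity_params = ap,
                     input_names = lst$input_names,
                     history = if (!is.null(lst$history)) {
                       as.data.frame(lst$history)
                     } else NULL,
                     best_epoch = lst$best_epoch),
                class = "neural_model")
    },
    ad_bounds = {
      nm <- unlist(lst$descriptors)
      structure(list(lo = setNames(unlist(lst$lo), nm),
                     hi = setNames(unlist(lst$hi), nm),
                     min = setNames(unlist(lst$min), nm),
                     max = setNames(unlist(lst$max), nm),
                     factor = lst$factor, epsilon = lst$epsilon),
                class = "ad_bounds")
    },
    scaling_params = scaling_from_list(lst),
    abc_report = {
      structure(list(folds = as.data.frame(lst$folds),
                     r2_pred_avg = lst$r2_pred_avg,
                     labels = factor(unlist(lst$labels),
                                     levels = c("A", "B", "C")),
                     r2_pred_method = lst$r2_pred_method),
                class = "abc_report")
    },
    stop("unknown serialized type: ", lst$type, call. = FALSE))
}

#' Serialize fitted models and reports to JSON
#'
#' Supports `linear_model`, `neural_model`, `ad_bounds`,
#' `scaling_params` and `abc_report` objects. Numeric values are written
#' at full precision; `read_model_json()` reconstructs an object of the
#' original class.
#'
#' @param x the object to write.
#' @param path JSON file path.
#' @export
write_model_json <- function(x, path) {
  jsonlite::write_json(model_to_list(x), path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  if (!file.exists(path)) stop_io("model file not found: %s", path)
  list_to_model(jsonlite::read_json(path, simplifyVector = TRUE))
}
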