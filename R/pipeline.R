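#' Configuration for the end-to-end screening pipeline
#'
#' Collects every tunable of the workflow in one validated object:
#' preprocessing thresholds, BMLR search settings, network training
#' settings, the applicability-domain factor, the screening shortlist
#' sizes, file locations and the single global seed from which all
#' randomness in the pipeline is derived. The configuration round-trips
#' unchanged through [write_config()]/[read_config()].
#'
#' @param out_dir directory receiving every artifact.
#' @param seed global integer seed.
#' @param n_compounds,n_descriptors,n_informative,noise_sd,n_library,frac_outside
#'   synthetic-data settings used by [cmd_simulate()].
#' @param variance_threshold,min_abs_r preprocessing filter thresholds.
#' @param exclude_descriptors descriptor names dropped before any filter —
#'   the configurable stand-in for manual expert inspection of chemically
#'   irrelevant descriptors.
#' @param k_max,max_intercorrelation,beam_width BMLR search settings.
#' @param arch,eta,alpha,max_epochs,patience,split_step network settings;
#'   `arch` lists the hidden layer sizes only (input size follows from
#'   `n_inputs`).
#' @param n_inputs number of network input descriptors.
#' @param ad_factor applicability-domain range augmentation factor.
#' @param top_n,top_fraction screening shortlist settings.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir = "qsar_run",
                            seed = 1L,
                            n_compounds = 150L,
                            n_descriptors = 30L,
                            n_informative = 5L,
                            noise_sd = 0.1,
                            n_library = 1000L,
                            frac_outside = 0.1,
                            variance_threshold = 1e-4,
                            min_abs_r = 0.2,
                            exclude_descriptors = character(0),
                            k_max = 5L,
                            max_intercorrelation = 0.8,
                            beam_width = 50L,
                            arch = c(5L, 3L),
                            eta = 0.05,
                            alpha = 0.5,
                            max_epochs = 1500L,
                            patience = 100L,
                            split_step = 5L,
                            n_inputs = 5L,
                            ad_factor = 0.3,
                            top_n = 100L,
                            top_fraction = 0.4) {
  cfg <- list(out_dir = out_dir, seed = as.integer(seed),
              n_compounds = as.integer(n_compounds),
              n_descriptors = as.integer(n_descriptors),
              n_informative = as.integer(n_informative),
              noise_sd = noise_sd,
              n_library = as.integer(n_library),
              frac_outside = frac_outside,
              variance_threshold = variance_threshold,
              min_abs_r = min_abs_r,
              exclude_descriptors = as.character(exclude_descriptors),
              k_max = as.integer(k_max),
              max_intercorrelation = max_intercorrelation,
              beam_width = as.integer(beam_width),
              arch = as.integer(arch),
              eta = eta, alpha = alpha,
              max_epochs = as.integer(max_epochs),
              patience = as.integer(patience),
              split_step = as.integer(split_step),
              n_inputs = as.integer(n_inputs),
              ad_factor = ad_factor,
              top_n = as.integer(top_n),
              top_fraction = top_fraction)
  validate_config(cfg)
  structure(cfg, class = "pipeline_config")
}

validate_config <- function(cfg) {
  ok <- cfg$variance_threshold >= 0 &&
    cfg$min_abs_r >= 0 && cfg$min_abs_r < 1 &&
    cfg$k_max >= 2L &&
    cfg$max_intercorrelation > 0 && cfg$max_intercorrelation <= 1 &&
    cfg$eta > 0 && cfg$alpha >= 0 && cfg$alpha < 1 &&
    cfg$patience >= 1L && cfg$ad_factor >= 0 &&
    cfg$top_fraction > 0 && cfg$top_fraction <= 1 &&
    cfg$noise_sd >= 0 && cfg$frac_outside >= 0 && cfg$frac_outside <= 1
  if (!ok) stop_validation("pipeline configuration has out-of-range values")
  invisible(cfg)
}

#' Write and read pipeline configurations
#'
#' JSON by default; files ending in `.yaml`/`.yml` use YAML when the
#' `yaml` package is available.
#'
#' @param config a [pipeline_config()].
#' @param path file path (`.json`, `.yaml` or `.yml`).
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  lst <- unclass(config)
  if (grepl("\\.ya?ml$", path) &&
      requireNamespace("yaml", quietly = TRUE)) {
    yaml::write_yaml(lst, path)
  } else {
    jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop_io("config file not found: %s", path)
  lst <- if (grepl("\\.ya?ml$", path) &&
             requireNamespace("yaml", quietly = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  do.call(pipeline_config, lst)
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(config), tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

pipeline_log <- function(cmd, config, inputs = character(), outputs = character()) {
  log <- list(command = cmd,
              package_version = as.character(utils::packageVersion("qsarscreen")),
              config_hash = config_hash(config),
              seed = config$seed,
              input_hashes = as.list(tools::md5sum(inputs[file.exists(inputs)])),
              outputs = outputs,
              timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  path <- file.path(config$out_dir, paste0(cmd, "_log.json"))
  jsonlite::write_json(log, path, auto_unbox = TRUE)
  message(sprintf("[%s] seed %d, config %s -> %s",
                  cmd, config$seed, substr(log$config_hash, 1, 8),
                  paste(basename(outputs), collapse = ", ")))
  invisible(log)
}

art <- function(config, name) file.path(config$out_dir, name)

#' Pipeline commands
#'
#' Each command reads and writes documented CSV/JSON artifacts under
#' `config$out_dir`, logs the package version, config hash, seed and
#' input hashes, and can be re-run individually:
#' \describe{
#'   \item{`cmd_simulate`}{generate the synthetic training dataset
#'     (`dataset.csv` + truth sidecar) and screening library
#'     (`library.csv`).}
#'   \item{`cmd_preprocess`}{variance and correlation filters; writes
#'     `dataset_filtered.csv` and `filter_log.json`.}
#'   \item{`cmd_fit_bmlr`}{BMLR search on the filtered table; writes one
#'     model JSON per size and `bmlr_selected.json` (best `R2_cv`).}
#'   \item{`cmd_abc_validate`}{ABC validation of the selected linear
#'     model; writes `abc_report.json`.}
#'   \item{`cmd_train_ann`}{input selection and network training; writes
#'     `ann_model.json` and `ann_history.csv`.}
#'   \item{`cmd_screen`}{prefilters the library, applies both models
#'     inside the applicability domain, writes `screening_ranked.csv`,
#'     `removal_log.json`, `ad_bounds.json` and `shortlist.csv`.}
#' }
#'
#' @param config a [pipeline_config()].
#' @return Each command invisibly returns its main in-memory artifact.
#' @name pipeline-commands
NULL

#' @rdname pipeline-commands
#' @export
cmd_simulate <- function(config) {
  validate_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  spec <- synthetic_spec(
    n_compounds = config$n_compounds,
    n_descriptors = config$n_descriptors,
    informative_indices = seq_len(config$n_informative),
    true_coefficients = c(1, seq(0.5, by = 0.25,
                                 length.out = config$n_informative)),
    noise_sd = config$noise_sd,
    near_constant_indices = config$n_descriptors,  # exercise the variance filter
    seed = derive_seed(config$seed, 1L))
  ds <- gen_linear_dataset(spec)
  write_dataset_csv(ds, art(config, "dataset.csv"),
                    truth_path = art(config, "dataset_truth.json"))
  bounds <- compute_ad(ds$descriptors[, seq_len(config$n_descriptors - 1L)],
                       factor = config$ad_factor)
  lib <- gen_screening_library(config$n_library, bounds,
                               frac_outside = config$frac_outside,
                               seed = derive_seed(config$seed, 2L))
  write_library_csv(lib, art(config, "library.csv"))
  pipeline_log("simulate", config,
               outputs = c(art(config, "dataset.csv"),
                           art(config, "library.csv")))
  invisible(list(dataset = ds, library = lib))
}

#' @rdname pipeline-commands
#' @export
cmd_preprocess <- function(config) {
  validate_config(config)
  ds <- read_dataset_csv(art(config, "dataset.csv"))
  D <- ds$descriptors
  excluded <- intersect(config$exclude_descriptors, colnames(D))
  if (length(excluded) > 0L) {
    D <- D[, setdiff(colnames(D), excluded), drop = FALSE]
  }
  vf <- variance_filter(D, config$variance_threshold)
  cf <- correlation_filter(vf, ds$activity, config$min_abs_r)
  out <- new_qsar_dataset(cf, ds$activity, ds$truth)
  write_dataset_csv(out, art(config, "dataset_filtered.csv"))
  jsonlite::write_json(
    list(excluded_by_config = excluded,
         variance_removed = attr(vf, "removed"),
         correlation_removed = attr(cf, "removed"),
         order = c("config_exclusions", "variance_filter",
                   "correlation_filter"),
         retained = colnames(cf)),
    art(config, "filter_log.json"), auto_unbox = TRUE)
  pipeline_log("preprocess", config,
               inputs = art(config, "dataset.csv"),
               outputs = art(config, "dataset_filtered.csv"))
  invisible(out)
}

#' @rdname pipeline-commands
#' @export
cmd_fit_bmlr <- function(config) {
  validate_config(config)
  ds <- read_dataset_csv(art(config, "dataset_filtered.csv"))
  res <- bmlr_search(ds$descriptors, ds$activity,
                     k_max = config$k_max,
                     max_intercorrelation = config$max_intercorrelation,
                     beam_width = config$beam_width)
  for (nm in names(res$models)) {
    write_model_json(res$models[[nm]],
                     art(config, sprintf("bmlr_%s.json", nm)))
  }
  cvs <- vapply(res$models, function(m) m$R2_cv, numeric(1))
  sel <- res$models[[which.max(cvs)]]
  write_model_json(sel, art(config, "bmlr_selected.json"))
  pipeline_log("fit_bmlr", config,
               inputs = art(config, "dataset_filtered.csv"),
               outputs = art(config, "bmlr_selected.json"))
  invisible(res)
}

#' @rdname pipeline-commands
#' @export
cmd_abc_validate <- function(config) {
  validate_config(config)
  ds <- read_dataset_csv(art(config, "dataset_filtered.csv"))
  model <- read_model_json(art(config, "bmlr_selected.json"))
  rep <- abc_validate(ds$descriptors, ds$activity, model$descriptor_names)
  write_model_json(rep, art(config, "abc_report.json"))
  pipeline_log("abc_validate", config,
               inputs = c(art(config, "dataset_filtered.csv"),
                          art(config, "bmlr_selected.json")),
               outputs = art(config, "abc_report.json"))
  invisible(rep)
}

#' @rdname pipeline-commands
#' @export
cmd_train_ann <- function(config) {
  validate_config(config)
  ds <- read_dataset_csv(art(config, "dataset_filtered.csv"))
  n_inputs <- min(config$n_inputs, ncol(ds$descriptors))
  inputs <- select_inputs(ds$descriptors, ds$activity, n_inputs = n_inputs,
                          step = config$split_step,
                          seed = derive_seed(config$seed, 3L))
  sub <- new_qsar_dataset(ds$descriptors[, inputs, drop = FALSE],
                          ds$activity, ds$truth)
  cfg <- train_config(eta = config$eta, alpha = config$alpha,
                      max_epochs = config$max_epochs,
                      patience = config$patience,
                      seed = derive_seed(config$seed, 4L))
  model <- train_ann(sub, arch = c(n_inputs, config$arch, 1L), config = cfg,
                     split_step = config$split_step)
  write_model_json(model, art(config, "ann_model.json"))
  write.csv(model$history, art(config, "ann_history.csv"), row.names = FALSE)
  pipeline_log("train_ann", config,
               inputs = art(config, "dataset_filtered.csv"),
               outputs = c(art(config, "ann_model.json"),
                           art(config, "ann_history.csv")))
  invisible(model)
}

#' @rdname pipeline-commands
#' @export
cmd_screen <- function(config) {
  validate_config(config)
  lib <- read_library_csv(art(config, "library.csv"))
  ann <- read_model_json(art(config, "ann_model.json"))
  mlr <- read_model_json(art(config, "bmlr_selected.json"))
  train <- read_dataset_csv(art(config, "dataset.csv"))
  pf <- prefilter_library(lib)
  needed <- unique(c(ann$input_names, mlr$descriptor_names))
  miss <- setdiff(needed, colnames(train$descriptors))
  if (length(miss) > 0L) {
    stop_validation("training table lacks model descriptor(s): %s",
                    paste(miss, collapse = ", "))
  }
  bounds <- compute_ad(train$descriptors[, needed, drop = FALSE],
                       factor = config$ad_factor)
  res <- consensus_screen(pf$library, ann, mlr, bounds)
  write.csv(res, art(config, "screening_ranked.csv"), row.names = FALSE)
  jsonlite::write_json(pf$removal_log, art(config, "removal_log.json"),
                       auto_unbox = TRUE)
  write_model_json(bounds, art(config, "ad_bounds.json"))
  short <- top_selection(res, n = config$top_n,
                         fraction = config$top_fraction)
  write.csv(short, art(config, "shortlist.csv"), row.names = FALSE)
  pipeline_log("screen", config,
               inputs = c(art(config, "library.csv"),
                          art(config, "ann_model.json"),
                          art(config, "bmlr_selected.json")),
               outputs = c(art(config, "screening_ranked.csv"),
                           art(config, "shortlist.csv")))
  invisible(res)
}

#' Run the full pipeline
#'
#' Executes [cmd_simulate()], [cmd_preprocess()], [cmd_fit_bmlr()],
#' [cmd_abc_validate()], [cmd_train_ann()] and [cmd_screen()] in order.
#'
#' @param config a [pipeline_config()].
#' @return Invisibly, the final `screening_result`.
#' @export
run_pipeline <- function(config) {
  cmd_simulate(config)
  cmd_preprocess(config)
  cmd_fit_bmlr(config)
  cmd_abc_validate(config)
  cmd_train_ann(config)
  invisible(cmd_screen(config))
}
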