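#' Published QSAR model statistics for three neurodegeneration targets
#'
#' Loads the statistics of previously published five-descriptor
#' multilinear logIC50 models for TrkA, NMDA and LRRK2 that ship with the
#' package: dataset sizes, the training/validation split sizes of the
#' companion neural-network models, the printed regression coefficients
#' with standard errors and t-statistics, overall fit statistics (R2,
#' R2_cv, s2, F), and the per-fold ABC-validation prediction R2 values
#' with their printed averages.
#'
#' These numbers serve as recomputation anchors: derived quantities —
#' the F statistic from (R2, N, k) via [f_statistic()], t-statistics from
#' coefficient/standard-error pairs, ABC averages from the per-fold
#' triples, and validation-set sizes from the every-fifth-compound split
#' rule — can be recomputed with the package and compared against the
#' printed values.
#'
#' @return Nested list keyed by target (`TrkA`, `NMDA`, `LRRK2`).
#' @export
reported_qsar_models <- function() {
  path <- system.file("extdata", "reported_qsar_models.json",
                      package = "qsarscreen", mustWork = TRUE)
  jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = TRUE)$targets
}
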