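#' Read an EEG recording from disk
#'
#' Two dialects are supported: European Data Format (`"edf"`, continuous
#' recordings with one sampling rate) and a plain-text matrix dialect
#' (`"matrix"`): a CSV of channels (rows) x samples (columns) accompanied by a
#' YAML sidecar `<path>.yaml` holding `fs`, `channel_names` and `reference`.
#' `"auto"` picks by file extension.
#'
#' @param path input file.
#' @param format `"auto"`, `"edf"` or `"matrix"`.
#' @return An [recording()] object with potentials in microvolts.
#' @export
read_recording <- function(path, format = c("auto", "edf", "matrix")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, edf = "edf", csv = "matrix", tsv = "matrix",
                     stop("cannot infer format from extension '", ext,
                          "'; pass format=", call. = FALSE))
  }
  switch(format,
         edf = read_edf(path),
         matrix = read_matrix_recording(path))
}

sidecar_path <- function(path) paste0(path, ".yaml")

read_matrix_recording <- function(path) {
  meta_path <- sidecar_path(path)
  if (!file.exists(meta_path))
    stop("matrix dialect requires a metadata sidecar: ", meta_path, call. = FALSE)
  meta <- yaml::read_yaml(meta_path)
  for (key in c("fs", "channel_names")) {
    if (is.null(meta[[key]]))
      stop("sidecar is missing required key '", key, "'", call. = FALSE)
  }
  sep <- if (tolower(tools::file_ext(path)) == "tsv") "\t" else ","
  dat <- as.matrix(utils::read.table(path, sep = sep, header = FALSE))
  dimnames(dat) <- NULL
  if (nrow(dat) != length(meta$channel_names))
    stop("data has ", nrow(dat), " rows but sidecar lists ",
         length(meta$channel_names), " channels", call. = FALSE)
  recording(dat, fs = meta$fs, channel_names = meta$channel_names,
            reference = if (is.null(meta$reference)) "common" else meta$reference)
}

#' Write an EEG recording to disk
#'
#' @param rec an [recording()] object.
#' @param path output file; `.edf` writes EDF, `.csv`/`.tsv` write the matrix
#'   dialect with its YAML sidecar.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  validate_recording(rec)
  ext <- tolower(tools::file_ext(path))
  if (ext == "edf") return(write_edf(rec, path))
  sep <- if (ext == "tsv") "\t" else ","
  utils::write.table(format(rec$data, digits = 15, trim = TRUE, scientific = TRUE),
                     path, sep = sep, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  yaml::write_yaml(list(fs = rec$fs, channel_names = as.list(rec$channel_names),
                        reference = rec$reference),
                   sidecar_path(path))
  invisible(path)
}

#' Write analysis result tables
#'
#' Writes the per-subject microstate metrics table and the correlation table
#' as TSV files with a fixed, documented column order, plus a JSON summary
#' with full float precision. Metrics columns: `subject`, then
#' `duration_MS1..MS4` (ms), `occurrence_MS1..MS4` (1/s),
#' `coverage_MS1..MS4` (%), then the 12 ordered transition probabilities
#' `t_MS1_MS2 .. t_MS4_MS3`. Correlation columns: `predictor`, `outcome`,
#' `r`, `p`, `n`, `adjusted_for`, `significant`, `significant_01`.
#'
#' @param metrics a data frame as returned by [metrics_table()].
#' @param correlations a data frame as returned by [correlation_table()].
#' @param path_prefix output path prefix; writes `<prefix>_metrics.tsv`,
#'   `<prefix>_correlations.tsv` and `<prefix>_summary.json`.
#' @return Named character vector of the files written, invisibly.
#' @export
write_results <- function(metrics, correlations, path_prefix) {
  if (is.null(metrics) || nrow(metrics) == 0L)
    stop("metrics table is empty", call. = FALSE)
  if (is.null(correlations) || nrow(correlations) == 0L)
    stop("correlations table is empty", call. = FALSE)
  files <- c(metrics = paste0(path_prefix, "_metrics.tsv"),
             correlations = paste0(path_prefix, "_correlations.tsv"),
             summary = paste0(path_prefix, "_summary.json"))
  write_tsv_full <- function(df, f) {
    num <- vapply(df, is.double, logical(1L))
    df[num] <- lapply(df[num], function(x) format(x, digits = 17, trim = TRUE))
    utils::write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write_tsv_full(metrics, files[["metrics"]])
  write_tsv_full(correlations, files[["correlations"]])
  summ <- list(
    n_subjects = length(unique(metrics$subject)),
    n_correlations = nrow(correlations),
    n_significant = sum(correlations$significant),
    metrics = metrics, correlations = correlations)
  jsonlite::write_json(summ, files[["summary"]], auto_unbox = TRUE,
                       digits = NA, dataframe = "columns")
  invisible(files)
}

#' Read back result tables written by [write_results()]
#' @param path_prefix the prefix passed to [write_results()].
#' @return list with elements `metrics` and `correlations`.
#' @export
read_results <- function(path_prefix) {
  rd <- function(f) utils::read.table(f, sep = "\t", header = TRUE,
                                      stringsAsFactors = FALSE)
  list(metrics = rd(paste0(path_prefix, "_metrics.tsv")),
       correlations = rd(paste0(path_prefix, "_correlations.tsv")))
}
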