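#' Write a recording to disk
#'
#' Two on-disk dialects are supported. `"matrix"` (the canonical format)
#' writes a tab-delimited samples-by-channels matrix `<base>_data.tsv` plus a
#' JSON header `<base>.json` holding `sampling_rate`, `channel_labels`,
#' `condition_intervals`, `condition_levels` and `subject_id`. `"edf"` writes
#' a 16-bit EDF file with a JSON sidecar for the condition intervals (EDF has
#' no native store for them), at the cost of 16-bit quantisation.
#'
#' @param rec An [eeg_recording].
#' @param path For `"matrix"`: the header path (`.json`, data file written
#'   next to it). For `"edf"`: the `.edf` path.
#' @param format `"matrix"` or `"edf"`.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path, format = c("matrix", "edf")) {
  format <- match.arg(format)
  if (!inherits(rec, "eeg_recording")) {
    abort_eeg("`rec` must be an eeg_recording.", class = "eegworkload_error_config")
  }
  if (format == "edf") return(write_edf(rec, path))

  base <- tools::file_path_sans_ext(path)
  data_file <- paste0(basename(base), "_data.tsv")
  header <- list(
    format = "eegworkload-matrix-v1",
    subject_id = rec$subject_id,
    sampling_rate = rec$sampling_rate,
    channel_labels = rec$channel_labels,
    condition_intervals = rec$condition_intervals,
    condition_levels = as.list(rec$condition_levels),
    data_file = data_file
  )
  jsonlite::write_json(header, paste0(base, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  mat <- t(rec$samples)  # samples x channels on disk
  colnames(mat) <- rec$channel_labels
  utils::write.table(format(mat, digits = 15, trim = TRUE, scientific = TRUE),
                     file.path(dirname(base), data_file),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a recording from disk
#'
#' @param path Path to a `.edf` file or to the JSON header of the
#'   matrix+header dialect (see [write_recording()]).
#' @param format `"auto"` (by extension), `"edf"` or `"matrix"`.
#' @return An [eeg_recording].
#' @export
read_recording <- function(path, format = c("auto", "edf", "matrix")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    abort_eeg(sprintf("File not found: %s", path),
              class = "eegworkload_error_parse")
  }
  if (format == "auto") {
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "matrix"
  }
  if (format == "edf") return(read_edf(path))

  header <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                     error = function(e) {
                       abort_eeg(sprintf("Malformed JSON header: %s",
                                         conditionMessage(e)),
                                 class = "eegworkload_error_parse")
                     })
  for (field in c("sampling_rate", "channel_labels", "data_file")) {
    if (is.null(header[[field]])) {
      abort_eeg(sprintf("Header is missing required field \"%s\".", field),
                class = "eegworkload_error_parse")
    }
  }
  data_path <- file.path(dirname(path), header$data_file)
  if (!file.exists(data_path)) {
    abort_eeg(sprintf("Data file not found: %s", data_path),
              class = "eegworkload_error_parse")
  }
  mat <- as.matrix(utils::read.table(data_path, header = TRUE, sep = "\t",
                                     check.names = FALSE))
  if (ncol(mat) != length(header$channel_labels)) {
    abort_eeg(sprintf(
      "Header lists %d channel_labels but the data matrix has %d columns.",
      length(header$channel_labels), ncol(mat)),
      class = "eegworkload_error_parse")
  }
  levels <- NULL
  if (!is.null(header$condition_levels)) {
    levels <- unlist(header$condition_levels)
    levels <- setNames(as.integer(levels), names(levels))
  }
  intervals <- if (!is.null(header$condition_intervals)) {
    as_tibble(header$condition_intervals)
  }
  eeg_recording(t(mat), header$sampling_rate, header$channel_labels,
                intervals, subject_id = header$subject_id %||% "unknown",
                condition_levels = levels)
}
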