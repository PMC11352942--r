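#' Construct a continuous EEG recording
#'
#' Lightweight container for one subject's continuous multichannel EEG:
#' a channels-by-time matrix in microvolts plus montage and condition
#' metadata. Most users will obtain recordings from [simulate_subject()] or
#' [read_recording()] rather than building them by hand.
#'
#' @param samples Numeric matrix, channels x time (microvolts).
#' @param sampling_rate Sampling rate in Hz.
#' @param channel_labels Character vector, one label per matrix row.
#' @param condition_intervals Tibble/data frame with columns `condition`,
#'   `start`, `end` (seconds); non-overlapping and inside the recording.
#' @param subject_id Subject identifier.
#' @param condition_levels Optional named integer vector mapping condition
#'   name to 0-based workload level.
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(samples, sampling_rate, channel_labels,
                          condition_intervals = NULL, subject_id = "s1",
                          condition_levels = NULL) {
  samples <- as.matrix(samples)
  if (!is_scalar_number(sampling_rate) || sampling_rate <= 0) {
    abort_eeg("`sampling_rate` must be a single positive number.",
              class = "eegworkload_error_config")
  }
  if (length(channel_labels) != nrow(samples)) {
    abort_eeg(sprintf(
      "channel_labels has %d entries but the sample matrix has %d rows.",
      length(channel_labels), nrow(samples)), class = "eegworkload_error_parse")
  }
  if (anyDuplicated(channel_labels)) {
    abort_eeg("Channel labels must be unique.", class = "eegworkload_error_config")
  }
  dur <- ncol(samples) / sampling_rate
  if (is.null(condition_intervals)) {
    condition_intervals <- tibble(condition = "all", start = 0, end = dur)
  }
  condition_intervals <- as_tibble(condition_intervals)
  ci <- condition_intervals[order(condition_intervals$start), ]
  if (any(ci$end > dur + 1e-9) || any(ci$start < 0) ||
      any(ci$end <= ci$start)) {
    abort_eeg("Condition intervals must lie within the recording duration.",
              class = "eegworkload_error_config")
  }
  if (nrow(ci) > 1 && any(ci$start[-1] < ci$end[-nrow(ci)] - 1e-9)) {
    abort_eeg("Condition intervals must not overlap.",
              class = "eegworkload_error_config")
  }
  rownames(samples) <- channel_labels
  structure(
    list(samples = samples,
         sampling_rate = sampling_rate,
         channel_labels = as.character(channel_labels),
         condition_intervals = condition_intervals,
         subject_id = subject_id,
         condition_levels = condition_levels),
    class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> subject %s: %d channels x %d samples (%.1f s @ %g Hz)\n",
              x$subject_id, nrow(x$samples), ncol(x$samples),
              ncol(x$samples) / x$sampling_rate, x$sampling_rate))
  cat("conditions:",
      paste(sprintf("%s [%g, %g)", x$condition_intervals$condition,
                    x$condition_intervals$start, x$condition_intervals$end),
            collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.eeg_recording <- function(x) dim(x$samples)

recording_duration <- function(rec) ncol(rec$samples) / rec$sampling_rate
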