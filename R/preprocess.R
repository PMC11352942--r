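#' Remove utility (non-cortical) channels
#'
#' @param rec An [eeg_recording].
#' @param utility_labels Labels to drop; defaults to the montage's standard
#'   utility set intersected with the recording's channels.
#' @return The recording without those channels, remaining order preserved.
#' @export
#' @examples
#' cfg <- sim_config(n_subjects = 1, duration_per_condition = 8,
#'                   sampling_rate = 128)
#' rec <- simulate_subject(cfg, 1)$recording
#' nrow(prune_channels(rec)$samples)  # 59
prune_channels <- function(rec, utility_labels = NULL) {
  if (is.null(utility_labels)) {
    utility_labels <- intersect(utility_channels(), rec$channel_labels)
  }
  unknown <- setdiff(utility_labels, rec$channel_labels)
  if (length(unknown) > 0) {
    abort_eeg(sprintf("Unknown channel label(s): %s",
                      paste(unknown, collapse = ", ")),
              class = "eegworkload_error_channel")
  }
  if (length(utility_labels) == 0) return(rec)
  keep <- !(rec$channel_labels %in% utility_labels)
  eeg_recording(rec$samples[keep, , drop = FALSE], rec$sampling_rate,
                rec$channel_labels[keep], rec$condition_intervals,
                subject_id = rec$subject_id,
                condition_levels = rec$condition_levels)
}

#' Common-average re-referencing
#'
#' Subtracts, at every time point, the mean across all channels, so that the
#' instantaneous channel mean is zero.
#'
#' @param rec An [eeg_recording] with at least two channels.
#' @return The re-referenced recording.
#' @export
rereference_average <- function(rec) {
  if (nrow(rec$samples) < 2) {
    abort_eeg("Average re-referencing needs at least 2 channels.",
              class = "eegworkload_error_config")
  }
  m <- colMeans(rec$samples)
  eeg_recording(sweep(rec$samples, 2, m), rec$sampling_rate,
                rec$channel_labels, rec$condition_intervals,
                subject_id = rec$subject_id,
                condition_levels = rec$condition_levels)
}

#' Zero-phase band-pass filtering
#'
#' Cascaded Butterworth high-pass (order 2) and low-pass (order 3) applied
#' forward and backward (`signal::filtfilt`), giving zero phase shift,
#' roughly 24 dB attenuation one octave below `low` and over 20 dB at
#' 1.5 x `high`. An optional mains notch (4 Hz-wide band-stop) can be added.
#'
#' @param rec An [eeg_recording].
#' @param low,high Pass-band edges in Hz, `0 < low < high < fs/2`.
#' @param notch Mains frequency in Hz (e.g. 50), or `NULL` for none.
#' @return The filtered recording (same length).
#' @export
bandpass_filter <- function(rec, low = 0.5, high = 80, notch = NULL) {
  fs <- rec$sampling_rate
  nyq <- fs / 2
  if (!is_scalar_number(low) || !is_scalar_number(high) ||
      low <= 0 || low >= high || high >= nyq) {
    abort_eeg("Band edges must satisfy 0 < low < high < sampling_rate/2.",
              class = "eegworkload_error_config")
  }
  hp <- signal::butter(2, low / nyq, type = "high")
  lp <- signal::butter(3, high / nyq, type = "low")
  nf <- NULL
  if (!is.null(notch)) {
    if (!is_scalar_number(notch) || notch - 2 <= 0 || notch + 2 >= nyq) {
      abort_eeg("`notch` must lie well inside (0, sampling_rate/2).",
                class = "eegworkload_error_config")
    }
    nf <- signal::butter(2, c(notch - 2, notch + 2) / nyq, type = "stop")
  }
  filt_one <- function(x) {
    y <- signal::filtfilt(hp, x)
    y <- signal::filtfilt(lp, y)
    if (!is.null(nf)) y <- signal::filtfilt(nf, y)
    y
  }
  out <- t(apply(rec$samples, 1, filt_one))
  eeg_recording(out, fs, rec$channel_labels, rec$condition_intervals,
                subject_id = rec$subject_id,
                condition_levels = rec$condition_levels)
}

#' Segment a recording into fixed-length epochs
#'
#' Epochs tile each condition interval left to right; a trailing partial
#' window is dropped; no epoch spans two conditions.
#'
#' @param rec An [eeg_recording].
#' @param epoch_length Epoch length in seconds.
#' @param overlap Fractional overlap between consecutive epochs, in `[0, 1)`.
#' @return An `eeg_epochs` object: an epochs x channels x time array plus a
#'   per-epoch label tibble (`epoch`, `subject`, `condition`, `level`,
#'   `t_start`).
#' @export
segment_epochs <- function(rec, epoch_length = 2, overlap = 0) {
  check_positive_scalar(epoch_length, "epoch_length")
  if (!is_scalar_number(overlap) || overlap < 0 || overlap >= 1) {
    abort_eeg("`overlap` must be in [0, 1).", class = "eegworkload_error_config")
  }
  fs <- rec$sampling_rate
  n_e <- round(epoch_length * fs)
  step <- max(1L, round(n_e * (1 - overlap)))
  ci <- rec$condition_intervals
  too_short <- ci$condition[(ci$end - ci$start) < epoch_length - 1e-9]
  if (length(too_short) > 0) {
    abort_eeg(sprintf(
      "Epoch length %g s exceeds condition interval(s): %s.",
      epoch_length, paste(too_short, collapse = ", ")),
      class = "eegworkload_error_config")
  }
  lev <- rec$condition_levels
  slices <- list()
  info <- list()
  for (i in seq_len(nrow(ci))) {
    s0 <- round(ci$start[i] * fs)
    s1 <- round(ci$end[i] * fs)
    starts <- seq(s0, s1 - n_e, by = step)
    for (st in starts) {
      slices[[length(slices) + 1L]] <- rec$samples[, (st + 1):(st + n_e),
                                                   drop = FALSE]
      info[[length(info) + 1L]] <- tibble(
        subject = rec$subject_id,
        condition = ci$condition[i],
        level = if (!is.null(lev)) unname(lev[ci$condition[i]]) else NA_integer_,
        t_start = st / fs)
    }
  }
  n_ep <- length(slices)
  n_ch <- nrow(rec$samples)
  data <- array(0, dim = c(n_ep, n_ch, n_e))
  for (j in seq_len(n_ep)) data[j, , ] <- slices[[j]]
  info <- bind_rows(info)
  info <- mutate(info, epoch = paste0(info$subject, "_e",
                                      sprintf("%04d", seq_len(n_ep))),
                 .before = 1)
  structure(
    list(data = data,
         sampling_rate = fs,
         epoch_length = epoch_length,
         channel_labels = rec$channel_labels,
         info = info),
    class = "eeg_epochs")
}

#' @export
print.eeg_epochs <- function(x, ...) {
  cat(sprintf("<eeg_epochs> %d epochs x %d channels x %d samples (%g s @ %g Hz)\n",
              dim(x$data)[1], dim(x$data)[2], dim(x$data)[3],
              x$epoch_length, x$sampling_rate))
  print(count(x$info, .data$condition, .data$level))
  invisible(x)
}

#' Combine epoch sets from several subjects
#'
#' @param ... `eeg_epochs` objects with identical montage, sampling rate and
#'   epoch length.
#' @return A single `eeg_epochs` object.
#' @export
bind_epochs <- function(...) {
  sets <- list(...)
  if (length(sets) == 1 && is.list(sets[[1]]) &&
      !inherits(sets[[1]], "eeg_epochs")) {
    sets <- sets[[1]]
  }
  ref <- sets[[1]]
  for (s in sets[-1]) {
    if (!identical(s$channel_labels, ref$channel_labels) ||
        s$sampling_rate != ref$sampling_rate ||
        s$epoch_length != ref$epoch_length) {
      abort_eeg("Epoch sets differ in montage, rate or epoch length.",
                class = "eegworkload_error_config")
    }
  }
  data <- do.call(abind_first, lapply(sets, function(s) s$data))
  structure(
    list(data = data, sampling_rate = ref$sampling_rate,
         epoch_length = ref$epoch_length,
         channel_labels = ref$channel_labels,
         info = bind_rows(lapply(sets, function(s) s$info))),
    class = "eeg_epochs")
}

# bind 3-d arrays along the first margin
abind_first <- function(...) {
  arrays <- list(...)
  d <- dim(arrays[[1]])
  total <- sum(vapply(arrays, function(a) dim(a)[1], 0))
  out <- array(0, dim = c(total, d[2], d[3]))
  at <- 0
  for (a in arrays) {
    n <- dim(a)[1]
    out[(at + 1):(at + n), , ] <- a
    at <- at + n
  }
  out
}
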