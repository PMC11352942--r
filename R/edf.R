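# Minimal EDF (European Data Format) codec: 16-bit continuous recordings,
# one-second data records. Written here because the R environment has no EDF
# package; covers exactly what this pipeline needs (no annotations, no
# discontinuous records). Condition intervals and workload levels, which EDF
# cannot carry, travel in a JSON sidecar written next to the .edf file.

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = -width)
}

edf_sidecar_path <- function(path) {
  paste0(tools::file_path_sans_ext(path), "_meta.json")
}

write_edf <- function(rec, path) {
  fs <- rec$sampling_rate
  if (fs != round(fs)) {
    abort_eeg("EDF export requires an integer sampling rate.",
              class = "eegworkload_error_parse")
  }
  n_samp <- ncol(rec$samples)
  if (n_samp %% fs != 0) {
    abort_eeg("EDF export requires a whole number of seconds of signal.",
              class = "eegworkload_error_parse")
  }
  n_rec <- n_samp %/% fs
  ns <- nrow(rec$samples)

  # symmetric physical range per channel; digital range -32768..32767
  pmax_ <- apply(abs(rec$samples), 1, max)
  pmax_ <- ifelse(pmax_ <= 0, 1, pmax_ * 1.0001)
  pmin_ <- -pmax_

  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  hdr <- paste0(
    edf_pad("0", 8),
    edf_pad(rec$subject_id, 80),
    edf_pad("eegworkload", 80),
    edf_pad("01.01.00", 8),
    edf_pad("00.00.00", 8),
    edf_pad(256 * (1 + ns), 8),
    edf_pad("", 44),
    edf_pad(n_rec, 8),
    edf_pad("1", 8),
    edf_pad(ns, 4)
  )
  sig <- paste0(
    paste(vapply(rec$channel_labels, edf_pad, "", width = 16), collapse = ""),
    paste(rep(edf_pad("", 80), ns), collapse = ""),
    paste(rep(edf_pad("uV", 8), ns), collapse = ""),
    paste(vapply(pmin_, function(p) edf_pad(formatC(p, format = "g", digits = 6), 8), ""), collapse = ""),
    paste(vapply(pmax_, function(p) edf_pad(formatC(p, format = "g", digits = 6), 8), ""), collapse = ""),
    paste(rep(edf_pad("-32768", 8), ns), collapse = ""),
    paste(rep(edf_pad("32767", 8), ns), collapse = ""),
    paste(rep(edf_pad("", 80), ns), collapse = ""),
    paste(rep(edf_pad(fs, 8), ns), collapse = ""),
    paste(rep(edf_pad("", 32), ns), collapse = "")
  )
  writeChar(paste0(hdr, sig), con, eos = NULL, useBytes = TRUE)

  scale <- (pmax_ - pmin_) / 65535
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1) * fs + 1):(r * fs)
    block <- rec$samples[, idx, drop = FALSE]
    dig <- round((block - pmin_) / scale) - 32768
    dig <- pmin(pmax(dig, -32768), 32767)
    writeBin(as.integer(t(dig)), con, size = 2, endian = "little")
  }

  meta <- list(
    subject_id = rec$subject_id,
    sampling_rate = fs,
    condition_intervals = rec$condition_intervals,
    condition_levels = as.list(rec$condition_levels)
  )
  jsonlite::write_json(meta, edf_sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  rd <- function(width) trimws(readChar(con, width, useBytes = TRUE))
  rd(8)                      # version
  patient <- rd(80)
  rd(80); rd(8); rd(8); rd(8); rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (is.na(ns) || ns < 1) {
    abort_eeg("Malformed EDF header: signal count.",
              class = "eegworkload_error_parse")
  }
  labels <- vapply(seq_len(ns), function(i) rd(16), "")
  for (i in seq_len(ns)) rd(80)   # transducer
  for (i in seq_len(ns)) rd(8)    # physical dimension
  pmin_ <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  pmax_ <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  dmin_ <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  dmax_ <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  for (i in seq_len(ns)) rd(80)   # prefiltering
  nr <- vapply(seq_len(ns), function(i) as.integer(rd(8)), 0L)
  for (i in seq_len(ns)) rd(32)
  if (length(unique(nr)) != 1) {
    abort_eeg("EDF files with mixed per-signal rates are not supported.",
              class = "eegworkload_error_parse")
  }
  fs <- nr[1] / rec_dur
  samples <- matrix(0, ns, n_rec * nr[1])
  scale <- (pmax_ - pmin_) / (dmax_ - dmin_)
  for (r in seq_len(n_rec)) {
    raw <- readBin(con, integer(), n = ns * nr[1], size = 2, endian = "little")
    block <- matrix(raw, nrow = nr[1], ncol = ns)
    idx <- ((r - 1) * nr[1] + 1):(r * nr[1])
    samples[, idx] <- t((block - rep(dmin_, each = nr[1])) *
                          rep(scale, each = nr[1]) + rep(pmin_, each = nr[1]))
  }

  meta_path <- edf_sidecar_path(path)
  intervals <- NULL; levels <- NULL; subject_id <- patient
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    intervals <- as_tibble(meta$condition_intervals)
    levels <- unlist(meta$condition_levels)
    levels <- setNames(as.integer(levels), names(levels))
    subject_id <- meta$subject_id %||% patient
  }
  eeg_recording(samples, fs, labels, intervals, subject_id = subject_id,
                condition_levels = levels)
}
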