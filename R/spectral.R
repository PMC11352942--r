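# Welch PSD and absolute band powers.

hann_window <- function(n) 0.5 * (1 - cos(2 * pi * (0:(n - 1)) / (n - 1)))

# Welch one-sided PSD for every (epoch, channel) series in an epochs array.
# Returns list(freq, psd) with psd dim = (n_freq, n_epoch, n_channel).
welch_psd_array <- function(data, fs, seg_seconds = 1, seg_overlap = 0.5) {
  n_ep <- dim(data)[1]; n_ch <- dim(data)[2]; n_t <- dim(data)[3]
  L <- min(n_t, round(seg_seconds * fs))
  step <- max(1L, round(L * (1 - seg_overlap)))
  starts <- seq(1, n_t - L + 1, by = step)
  w <- hann_window(L)
  U <- sum(w^2)
  n_keep <- floor(L / 2) + 1
  acc <- matrix(0, n_keep, n_ep * n_ch)
  for (s in starts) {
    seg <- data[, , s:(s + L - 1), drop = FALSE]
    m <- matrix(seg, nrow = n_ep * n_ch, ncol = L)   # rows: epoch x channel
    m <- sweep(m, 2, w, "*")
    Fm <- mvfft(t(m))                                # L x (n_ep*n_ch)
    acc <- acc + abs(Fm[seq_len(n_keep), , drop = FALSE])^2
  }
  psd <- acc / (fs * U * length(starts))
  # one-sided: double everything but DC (and Nyquist when L even)
  dbl <- rep(2, n_keep); dbl[1] <- 1
  if (L %% 2 == 0) dbl[n_keep] <- 1
  psd <- psd * dbl
  list(freq = (seq_len(n_keep) - 1) * fs / L,
       df = fs / L,
       psd = array(psd, dim = c(n_keep, n_ep, n_ch)))
}

#' Absolute band powers per epoch and channel
#'
#' Estimates the PSD of every epoch/channel with Welch's method (Hann
#' window, segments of `seg_seconds`, `seg_overlap` fractional overlap) and
#' integrates it over each band, yielding absolute band power in microvolts
#' squared.
#'
#' @param epochs An `eeg_epochs` object from [segment_epochs()].
#' @param bands Band definitions, see [eeg_bands()].
#' @param seg_seconds Welch segment length in seconds (capped at the epoch
#'   length).
#' @param seg_overlap Fractional overlap between Welch segments.
#' @return A tibble of class `band_power_tbl`, one row per epoch x channel,
#'   with the epoch label columns plus one numeric column per band.
#' @export
#' @examples
#' cfg <- sim_config(n_subjects = 1, duration_per_condition = 8,
#'                   sampling_rate = 128)
#' ep <- segment_epochs(simulate_subject(cfg, 1)$recording)
#' band_powers(ep)
band_powers <- function(epochs, bands = eeg_bands(), seg_seconds = 1,
                        seg_overlap = 0.5) {
  if (!inherits(epochs, "eeg_epochs")) {
    abort_eeg("`epochs` must be an eeg_epochs object.",
              class = "eegworkload_error_config")
  }
  fs <- epochs$sampling_rate
  if (any(bands$high > fs / 2)) {
    abort_eeg("Band edges must not exceed the Nyquist frequency.",
              class = "eegworkload_error_config")
  }
  if (epochs$epoch_length < 2 / bands$low[1]) {
    abort_eeg(sprintf(
      "Epoch length %g s is too short for the %g Hz band edge.",
      epochs$epoch_length, bands$low[1]), class = "eegworkload_error_config")
  }
  w <- welch_psd_array(epochs$data, fs, seg_seconds, seg_overlap)
  n_ep <- dim(epochs$data)[1]; n_ch <- dim(epochs$data)[2]
  out <- epochs$info[rep(seq_len(n_ep), times = n_ch), ]
  out$channel <- rep(epochs$channel_labels, each = n_ep)
  for (i in seq_len(nrow(bands))) {
    sel <- w$freq >= bands$low[i] & w$freq < bands$high[i]
    bp <- apply(w$psd[sel, , , drop = FALSE], c(2, 3), sum) * w$df
    out[[bands$band[i]]] <- as.vector(bp)
  }
  out <- as_tibble(out)
  attr(out, "bands") <- bands
  attr(out, "psd_settings") <- list(estimator = "welch", window = "hann",
                                    seg_seconds = seg_seconds,
                                    seg_overlap = seg_overlap,
                                    sampling_rate = fs,
                                    epoch_length = epochs$epoch_length)
  class(out) <- c("band_power_tbl", class(out))
  out
}
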