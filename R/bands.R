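#' Frequency band definitions
#'
#' The five canonical EEG rhythms as half-open frequency intervals
#' `[low, high)`. Defaults: delta 1-4, theta 4-8, alpha 8-13, beta 13-30,
#' gamma 30-45 Hz. The gamma edge is kept below a 50 Hz mains notch.
#'
#' @param delta,theta,alpha,beta,gamma Length-2 numeric vectors `c(low, high)`
#'   in Hz.
#' @return A tibble with columns `band`, `low`, `high`, class `eeg_bands`.
#'   Bands must be non-overlapping, contiguous and ascending.
#' @export
#' @examples
#' eeg_bands()
eeg_bands <- function(delta = c(1, 4), theta = c(4, 8), alpha = c(8, 13),
                      beta = c(13, 30), gamma = c(30, 45)) {
  edges <- list(delta = delta, theta = theta, alpha = alpha,
                beta = beta, gamma = gamma)
  for (nm in names(edges)) {
    e <- edges[[nm]]
    if (length(e) != 2L || !is.numeric(e) || e[1] >= e[2]) {
      abort_eeg(sprintf("Band `%s` must be c(low, high) with low < high.", nm),
                class = "eegworkload_error_config")
    }
  }
  bands <- tibble(
    band = names(edges),
    low = map_dbl(edges, 1),
    high = map_dbl(edges, 2)
  )
  # contiguous ascending: each band starts where the previous one ends
  if (any(bands$low[-1] != bands$high[-nrow(bands)])) {
    abort_eeg("Bands must be contiguous and ascending.",
              class = "eegworkload_error_config")
  }
  class(bands) <- c("eeg_bands", class(bands))
  bands
}

band_names <- function(bands) bands$band
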