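#' The 26-indicator spectral catalogue
#'
#' Scalar indicators formed from the five absolute band powers. Indicators
#' 1-13 are the conventional workload indicators built from delta, theta,
#' alpha and beta; indicators 14-26 are their gamma-bearing counterparts.
#' Absolute-energy indicators (1-5, 14-16) carry units of microvolts
#' squared; all others are dimensionless ratios.
#'
#' @return A tibble with columns `indicator_id`, `name`, `absolute` (energy
#'   vs ratio) and `uses_gamma`.
#' @export
#' @examples
#' indicator_catalog()
indicator_catalog <- function() {
  tibble(
    indicator_id = 1:26,
    name = c(
      "delta", "theta", "alpha", "beta",
      "delta+beta+theta+alpha",
      "delta/(delta+beta+theta+alpha)",
      "theta/(delta+beta+theta+alpha)",
      "alpha/(delta+beta+theta+alpha)",
      "beta/(delta+beta+theta+alpha)",
      "theta/beta", "alpha/beta",
      "(alpha+theta)/beta", "(alpha+theta)/(alpha+beta)",
      "gamma",
      "delta+beta+theta+alpha+gamma",
      "beta+theta+alpha+gamma",
      "gamma/delta", "gamma/theta", "gamma/alpha", "gamma/beta",
      "gamma/(alpha+beta)", "gamma/(theta+beta)", "gamma/(theta+alpha)",
      "gamma/(theta+beta+alpha)",
      "gamma/(delta+beta+theta+alpha)",
      "gamma/(delta+beta+theta+alpha+gamma)"
    ),
    absolute = 1:26 %in% c(1:5, 14:16),
    uses_gamma = 1:26 >= 14
  )
}

# numerator / denominator of each catalogue formula, given band power vectors
indicator_terms <- function(id, d, t, a, b, g) {
  s4 <- d + b + t + a
  switch(as.character(id),
    "1" = list(num = d, den = NULL),
    "2" = list(num = t, den = NULL),
    "3" = list(num = a, den = NULL),
    "4" = list(num = b, den = NULL),
    "5" = list(num = s4, den = NULL),
    "6" = list(num = d, den = s4),
    "7" = list(num = t, den = s4),
    "8" = list(num = a, den = s4),
    "9" = list(num = b, den = s4),
    "10" = list(num = t, den = b),
    "11" = list(num = a, den = b),
    "12" = list(num = a + t, den = b),
    "13" = list(num = a + t, den = a + b),
    "14" = list(num = g, den = NULL),
    "15" = list(num = s4 + g, den = NULL),
    "16" = list(num = b + t + a + g, den = NULL),
    "17" = list(num = g, den = d),
    "18" = list(num = g, den = t),
    "19" = list(num = g, den = a),
    "20" = list(num = g, den = b),
    "21" = list(num = g, den = a + b),
    "22" = list(num = g, den = t + b),
    "23" = list(num = g, den = t + a),
    "24" = list(num = g, den = t + b + a),
    "25" = list(num = g, den = s4),
    "26" = list(num = g, den = s4 + g),
    abort_eeg(sprintf("Unknown indicator id %s (catalogue is 1..26).", id),
              class = "eegworkload_error_config")
  )
}

#' Compute spectral indicators from band powers
#'
#' Evaluates catalogue formulas element-wise for every epoch/channel.
#'
#' @param bp A `band_power_tbl` from [band_powers()].
#' @param ids Indicator ids to compute (default all 26).
#' @param on_zero_denominator `"error"` (default) aborts identifying the
#'   offending epoch/channel; `"mask"` emits `NA` there instead.
#' @return A long tibble of class `indicator_tbl`: epoch label columns plus
#'   `channel`, `indicator_id`, `name`, `value`.
#' @export
compute_indicators <- function(bp, ids = 1:26,
                               on_zero_denominator = c("error", "mask")) {
  on_zero_denominator <- match.arg(on_zero_denominator)
  need <- c("delta", "theta", "alpha", "beta", "gamma", "channel")
  if (!all(need %in% names(bp))) {
    abort_eeg("`bp` must be a band-power table with the five band columns.",
              class = "eegworkload_error_config")
  }
  if (!all(ids %in% 1:26)) {
    abort_eeg("Indicator ids must be within 1..26.",
              class = "eegworkload_error_config")
  }
  cat_tbl <- indicator_catalog()
  info_cols <- intersect(c("epoch", "subject", "condition", "level",
                           "t_start", "channel"), names(bp))
  pieces <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    id <- ids[i]
    tm <- indicator_terms(id, bp$delta, bp$theta, bp$alpha, bp$beta, bp$gamma)
    if (is.null(tm$den)) {
      value <- tm$num
    } else {
      bad <- tm$den == 0
      if (any(bad)) {
        if (on_zero_denominator == "error") {
          first <- which(bad)[1]
          abort_eeg(sprintf(
            "Zero denominator for indicator %d at epoch %s, channel %s.",
            id, bp$epoch[first], bp$channel[first]),
            class = "eegworkload_error_degenerate")
        }
        value <- ifelse(bad, NA_real_, tm$num / tm$den)
      } else {
        value <- tm$num / tm$den
      }
    }
    piece <- bp[info_cols]
    piece$indicator_id <- id
    piece$name <- cat_tbl$name[id]
    piece$value <- value
    pieces[[i]] <- piece
  }
  out <- as_tibble(bind_rows(pieces))
  attr(out, "bands") <- attr(bp, "bands")
  attr(out, "psd_settings") <- attr(bp, "psd_settings")
  class(out) <- c("indicator_tbl", class(out))
  out
}

#' @rdname compute_indicators
#' @param id A single indicator id.
#' @export
compute_indicator <- function(bp, id,
                              on_zero_denominator = c("error", "mask")) {
  if (length(id) != 1) {
    abort_eeg("`id` must be a single indicator id.",
              class = "eegworkload_error_config")
  }
  compute_indicators(bp, ids = id, on_zero_denominator = on_zero_denominator)
}

#' Pivot one indicator to an epochs-by-channels matrix
#'
#' @param ind An `indicator_tbl`.
#' @param id Indicator id to extract; may be omitted when `ind` holds a
#'   single indicator.
#' @return A list with `values` (epochs x channels matrix, columns named by
#'   channel) and `info` (one row per epoch: subject, condition, level).
#' @export
indicator_matrix <- function(ind, id = NULL) {
  if (is.null(id)) {
    ids <- unique(ind$indicator_id)
    if (length(ids) != 1) {
      abort_eeg("`ind` holds several indicators; supply `id`.",
                class = "eegworkload_error_config")
    }
    id <- ids
  }
  sub <- ind[ind$indicator_id == id, ]
  if (nrow(sub) == 0) {
    abort_eeg(sprintf("Indicator %s not present in the table.", id),
              class = "eegworkload_error_config")
  }
  wide <- pivot_wider(sub[c("epoch", "channel", "value")],
                      names_from = "channel", values_from = "value")
  info <- distinct(sub[intersect(c("epoch", "subject", "condition", "level"),
                                 names(sub))])
  info <- info[match(wide$epoch, info$epoch), ]
  values <- as.matrix(wide[-1])
  rownames(values) <- wide$epoch
  list(values = values, info = as_tibble(info))
}
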