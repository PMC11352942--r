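# internal helpers shared across modules

# stop with a classed condition so callers/tests can target errors precisely
abort_eeg <- function(msg, class = "eegworkload_error", ...) {
  rlang::abort(msg, class = class, ...)
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

check_positive_scalar <- function(x, name) {
  if (!is_scalar_number(x) || x <= 0) {
    abort_eeg(sprintf("`%s` must be a single positive number.", name),
              class = "eegworkload_error_config")
  }
  invisible(x)
}

# derive a per-unit seed from a master seed; kept below 2^31
derive_seed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + index * 16807) %% 2147483587)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
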