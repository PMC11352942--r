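#' Workload labelling schemes
#'
#' Maps the five experimental conditions onto 2-4 ordered workload classes.
#' The condition order follows the subjective-workload (NASA-TLX) ranking:
#' rest < scenario1 < scenario2 < scenario4 < scenario3. Scenario 4 is
#' grouped with scenario 3 as "high" wherever fewer classes than conditions
#' are available.
#'
#' Built-in schemes:
#' \describe{
#'   \item{resting_working}{rest vs all four scenarios (2 classes).}
#'   \item{zero_lowmed_high}{rest / scenario1+scenario2 / scenario4+scenario3
#'     (3 classes).}
#'   \item{zero_low_medhigh}{rest / scenario1 / scenario2+scenario4+scenario3
#'     (3 classes).}
#'   \item{zero_low_med_high}{rest / scenario1 / scenario2 /
#'     scenario4+scenario3 (4 classes).}
#' }
#'
#' @param name One of the built-in scheme names, or `"custom"` with
#'   `mapping` supplied.
#' @param mapping For `"custom"`: a named character vector, condition ->
#'   class.
#' @param conditions Condition names in ascending workload order.
#' @return A tibble of class `label_scheme` with columns `condition`,
#'   `class` (factor, class order = first appearance along the workload
#'   order).
#' @export
#' @examples
#' label_scheme("zero_low_med_high")
label_scheme <- function(name = c("zero_low_med_high", "resting_working",
                                  "zero_lowmed_high", "zero_low_medhigh",
                                  "custom"),
                         mapping = NULL,
                         conditions = c("rest", "scenario1", "scenario2",
                                        "scenario4", "scenario3")) {
  name <- match.arg(name)
  map <- switch(name,
    resting_working = c(rest = "resting", scenario1 = "working",
                        scenario2 = "working", scenario4 = "working",
                        scenario3 = "working"),
    zero_lowmed_high = c(rest = "zero", scenario1 = "low_medium",
                         scenario2 = "low_medium", scenario4 = "high",
                         scenario3 = "high"),
    zero_low_medhigh = c(rest = "zero", scenario1 = "low",
                         scenario2 = "medium_high", scenario4 = "medium_high",
                         scenario3 = "medium_high"),
    zero_low_med_high = c(rest = "zero", scenario1 = "low",
                          scenario2 = "medium", scenario4 = "high",
                          scenario3 = "high"),
    custom = mapping
  )
  if (is.null(map)) {
    abort_eeg("A custom scheme needs a `mapping` (condition -> class).",
              class = "eegworkload_error_config")
  }
  missing_cond <- setdiff(conditions, names(map))
  if (length(missing_cond) > 0) {
    abort_eeg(sprintf("Scheme is missing condition(s): %s",
                      paste(missing_cond, collapse = ", ")),
              class = "eegworkload_error_config")
  }
  map <- map[conditions]
  classes <- unique(unname(map))
  if (length(classes) < 2 || length(classes) > 4) {
    abort_eeg("A scheme must define between 2 and 4 classes.",
              class = "eegworkload_error_config")
  }
  out <- tibble(condition = conditions,
                class = factor(unname(map), levels = classes))
  attr(out, "scheme_name") <- name
  class(out) <- c("label_scheme", class(out))
  out
}

#' Attach workload classes to epoch-level data
#'
#' @param x A tibble with a `condition` column (epoch info, band powers or
#'   indicator values), or an `eeg_epochs` object (its info tibble is
#'   labelled).
#' @param scheme A [label_scheme()].
#' @return `x` (or the epochs' info tibble) with a `class` factor column.
#' @export
apply_label_scheme <- function(x, scheme = label_scheme("zero_low_med_high")) {
  if (inherits(x, "eeg_epochs")) x <- x$info
  if (!("condition" %in% names(x))) {
    abort_eeg("`x` must have a `condition` column.",
              class = "eegworkload_error_config")
  }
  unknown <- setdiff(unique(x$condition), scheme$condition)
  if (length(unknown) > 0) {
    abort_eeg(sprintf("Condition(s) not covered by the scheme: %s",
                      paste(unknown, collapse = ", ")),
              class = "eegworkload_error_config")
  }
  idx <- match(x$condition, scheme$condition)
  x$class <- scheme$class[idx]
  x
}
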