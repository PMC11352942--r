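# broom-style tidiers for the package's result objects

#' @export
tidy.indicator_evaluation <- function(x, ...) {
  out <- as_tibble(x)
  class(out) <- setdiff(class(out), "indicator_evaluation")
  out
}

#' @export
glance.indicator_evaluation <- function(x, ...) {
  tibble(n_indicators = nrow(x),
         n_channels = attr(x, "n_channels") %||% NA_integer_,
         n_epochs = attr(x, "n_epochs") %||% NA_integer_,
         top_indicator_id = x$indicator_id[x$rank == 1],
         top_indicator = x$name[x$rank == 1],
         top_phi = x$phi[x$rank == 1])
}

#' @export
tidy.phi_metric <- function(x, ...) {
  tibble(D = x$D, R = x$R, phi = x$phi,
         n_epochs = x$n_epochs, n_channels = x$n_channels)
}

#' @export
tidy.loso_report <- function(x, ...) {
  out <- as_tibble(x)
  out$params <- NULL
  class(out) <- setdiff(class(out), "loso_report")
  out
}

#' @export
glance.loso_report <- function(x, ...) {
  tibble(n_subjects = nrow(x),
         mean_accuracy = mean(x$accuracy),
         min_accuracy = min(x$accuracy),
         max_accuracy = max(x$accuracy),
         mean_f1 = mean(x$f1),
         mean_auc = mean(x$auc, na.rm = TRUE))
}

#' @export
tidy.channel_ranking <- function(x, ...) {
  out <- as_tibble(x)
  out$subject <- attr(x, "subject")
  class(out) <- setdiff(class(out), "channel_ranking")
  out
}

#' @export
tidy.channel_frequency <- function(x, ...) {
  out <- as_tibble(x)
  class(out) <- setdiff(class(out), "channel_frequency")
  out
}

#' @export
tidy.combination_result <- function(x, ...) {
  out <- as_tibble(x)
  out$report <- NULL
  class(out) <- setdiff(class(out), "combination_result")
  out
}

#' @export
glance.combination_result <- function(x, ...) {
  best <- x[1, ]
  tibble(n_combinations = nrow(x),
         best_combo = best$combo,
         best_min_accuracy = best$min_accuracy,
         best_mean_accuracy = best$mean_accuracy)
}

#' @export
tidy.consensus_report <- function(x, ...) x$table

#' @export
glance.consensus_report <- function(x, ...) {
  tibble(spearman_rho = x$spearman_rho, n_indicators = nrow(x$table))
}

#' @export
glance.workload_model <- function(x, ...) {
  tibble(classifier = x$cfg$classifier,
         n_features = length(x$feature_names),
         n_classes = length(x$class_levels),
         params = paste(names(x$params), unlist(lapply(x$params, format)),
                        sep = "=", collapse = ", "))
}
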