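# ggplot2 visualisations for the main result types

#' @importFrom ggplot2 autoplot ggplot aes geom_col geom_point geom_hline
#'   geom_line geom_boxplot labs scale_fill_manual theme_minimal
#'   element_text theme
NULL

#' @export
ggplot2::autoplot

#' Plot an indicator evaluation
#'
#' Bar chart of the evaluation statistic phi per indicator, gamma-bearing
#' indicators highlighted.
#'
#' @param object An `indicator_evaluation`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.indicator_evaluation <- function(object, ...) {
  df <- tidy(object)
  df$indicator <- factor(df$indicator_id, levels = df$indicator_id[order(df$rank)])
  ggplot(df, aes(x = .data$indicator, y = .data$phi, fill = .data$uses_gamma)) +
    geom_col() +
    scale_fill_manual(values = c(`FALSE` = "grey55", `TRUE` = "#2c7fb8"),
                      name = "gamma-bearing") +
    labs(x = "indicator (ranked)", y = "phi = D - R (bits)",
         title = "mRMR indicator evaluation") +
    theme_minimal() +
    theme(axis.text.x = element_text(angle = 90, vjust = 0.5))
}

#' Plot cross-subject channel frequencies
#'
#' @param object A `channel_frequency`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.channel_frequency <- function(object, ...) {
  df <- tidy(object)
  df$channel <- factor(df$channel, levels = df$channel)
  ggplot(df, aes(x = .data$channel, y = .data$frequency,
                 fill = .data$candidate)) +
    geom_col() +
    geom_hline(yintercept = attr(object, "threshold"), linetype = "dashed") +
    scale_fill_manual(values = c(`FALSE` = "grey70", `TRUE` = "#31a354"),
                      name = "candidate") +
    labs(x = NULL, y = sprintf("fraction of subjects (top %d)",
                               attr(object, "top_k")),
         title = "Channel occurrence across subjects") +
    theme_minimal() +
    theme(axis.text.x = element_text(angle = 90, vjust = 0.5))
}

#' Plot a leave-one-subject-out report
#'
#' @param object A `loso_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.loso_report <- function(object, ...) {
  df <- tidy(object)
  long <- pivot_longer(df[c("subject", "accuracy", "f1", "auc")],
                       -"subject", names_to = "metric")
  ggplot(long, aes(x = .data$subject, y = .data$value,
                   colour = .data$metric, group = .data$metric)) +
    geom_point() + geom_line() +
    labs(x = "held-out subject", y = "metric value",
         title = "Leave-one-subject-out performance") +
    theme_minimal() +
    theme(axis.text.x = element_text(angle = 45, hjust = 1))
}

#' Plot channel-combination stability
#'
#' @param object A `combination_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.combination_result <- function(object, ...) {
  df <- tidy(object)
  df$combo <- factor(df$combo, levels = rev(df$combo))
  long <- pivot_longer(df[c("combo", "size", "min_accuracy", "mean_accuracy")],
                       c("min_accuracy", "mean_accuracy"),
                       names_to = "summary")
  ggplot(long, aes(x = .data$value, y = .data$combo,
                   colour = .data$summary)) +
    geom_point() +
    labs(x = "held-out accuracy", y = NULL,
         title = "Channel combinations (sorted by stability)") +
    theme_minimal()
}

#' Band power against workload level
#'
#' Boxplots of one channel's absolute band power per workload level.
#'
#' @param bp A `band_power_tbl`.
#' @param channel Channel label.
#' @param band Band name (default `"gamma"`).
#' @return A ggplot object.
#' @export
plot_band_power <- function(bp, channel, band = "gamma") {
  df <- bp[bp$channel == channel, ]
  if (nrow(df) == 0) {
    abort_eeg(sprintf("Unknown channel label(s): %s", channel),
              class = "eegworkload_error_channel")
  }
  ggplot(df, aes(x = factor(.data$level), y = .data[[band]])) +
    geom_boxplot() +
    labs(x = "workload level", y = sprintf("%s band power (uV^2)", band),
         title = sprintf("Channel %s", channel)) +
    theme_minimal()
}
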