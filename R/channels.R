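#' Greedy mRMR channel screening
#'
#' Ranks channels for one indicator by the incremental
#' minimum-redundancy-maximum-relevance criterion (difference form): the
#' first channel maximises the channel-label mutual information; each
#' following channel maximises relevance minus its mean MI with the
#' channels already selected. Ties break by channel label, lexicographically.
#'
#' @param x A single-indicator `indicator_tbl` (typically one subject's
#'   epochs) or an epochs x channels matrix.
#' @param labels Per-epoch workload labels; defaults to the table's `level`.
#' @param k Number of channels to select.
#' @param cfg An [evaluation_config()] (shared discretization).
#' @return A tibble of class `channel_ranking`: `rank`, `channel`, `score`
#'   (the incremental criterion at selection time), `relevance`.
#' @export
greedy_mrmr_channels <- function(x, labels = NULL, k = 10,
                                 cfg = evaluation_config()) {
  im <- as_values_matrix(x)
  ch <- resolve_channels(cfg, colnames(im$values))
  V <- im$values[, ch, drop = FALSE]
  labels <- resolve_labels(labels, im, nrow(V))
  if (!is_scalar_number(k) || k < 1 || k > length(ch)) {
    abort_eeg(sprintf("`k` must be between 1 and the %d channels.",
                      length(ch)), class = "eegworkload_error_config")
  }
  cm <- code_matrix(V, cfg$scheme)
  rel <- relevance_mi(cm$codes, cm$n_bins, labels)
  names(rel) <- ch

  selected <- character(0)
  scores <- numeric(0)
  # cache MI columns against already-selected channels
  red <- matrix(NA_real_, nrow = length(ch), ncol = 0,
                dimnames = list(ch, NULL))
  for (step in seq_len(k)) {
    remaining <- setdiff(ch, selected)
    crit <- if (step == 1) {
      rel[remaining]
    } else {
      rel[remaining] - rowMeans(red[remaining, , drop = FALSE])
    }
    pick <- remaining[order(-crit[remaining], remaining)][1]
    selected <- c(selected, pick)
    scores <- c(scores, unname(crit[pick]))
    if (step < k) {
      jp <- match(pick, ch)
      mi_col <- vapply(seq_along(ch), function(j) {
        mi_from_counts(joint_counts(cm$codes[, j], cm$n_bins[j],
                                    cm$codes[, jp], cm$n_bins[jp]))
      }, 0)
      red <- cbind(red, mi_col)
    }
  }
  out <- tibble(rank = seq_len(k), channel = selected, score = scores,
                relevance = unname(rel[selected]))
  attr(out, "subject") <- if (!is.null(im$info) && "subject" %in% names(im$info))
    unique(im$info$subject) else NA_character_
  attr(out, "indicator_id") <- if (inherits(x, "indicator_tbl"))
    unique(x$indicator_id) else NA_integer_
  attr(out, "channels") <- ch
  class(out) <- c("channel_ranking", class(out))
  out
}

#' Cross-subject channel frequency aggregation
#'
#' How often each channel appears in subjects' top-`top_k` mRMR rankings;
#' channels at or above `threshold` are flagged as candidates for
#' few-channel detection.
#'
#' @param rankings A list of `channel_ranking` objects (one per subject).
#' @param top_k Depth of each subject's list to consider.
#' @param threshold Candidate flagging threshold on the frequency (default
#'   0.8).
#' @return A tibble of class `channel_frequency`: `channel`, `n_subjects`,
#'   `frequency`, `candidate`, sorted by decreasing frequency.
#' @export
aggregate_frequency <- function(rankings, top_k = 10, threshold = 0.8) {
  if (inherits(rankings, "channel_ranking")) rankings <- list(rankings)
  if (length(rankings) < 1) {
    abort_eeg("Supply at least one channel ranking.",
              class = "eegworkload_error_config")
  }
  montages <- lapply(rankings, function(r) sort(attr(r, "channels")))
  if (length(unique(vapply(montages, paste, "", collapse = "|"))) != 1) {
    abort_eeg("Rankings come from inconsistent montages.",
              class = "eegworkload_error_channel")
  }
  n_subj <- length(rankings)
  tops <- lapply(rankings, function(r) head(r$channel, top_k))
  counts <- table(unlist(tops))
  out <- tibble(channel = names(counts),
                n_subjects = as.integer(counts),
                frequency = as.numeric(counts) / n_subj)
  out <- mutate(out, candidate = .data$frequency >= threshold)
  out <- arrange(out, desc(.data$frequency), .data$channel)
  attr(out, "top_k") <- top_k
  attr(out, "threshold") <- threshold
  attr(out, "n_rankings") <- n_subj
  class(out) <- c("channel_frequency", class(out))
  out
}

#' Enumerate unordered channel combinations
#'
#' @param candidates Channel labels to combine.
#' @param size Combination size (>= 1, <= number of candidates).
#' @return A tibble with `combo` (label, channels joined by `+`) and
#'   `channels` (list column of sorted label vectors), in lexicographic
#'   order.
#' @export
#' @examples
#' nrow(enumerate_combinations(informative_channels(), 2))  # 15
#' nrow(enumerate_combinations(informative_channels(), 3))  # 20
enumerate_combinations <- function(candidates, size) {
  if (!is_scalar_number(size) || size < 1 || size != round(size)) {
    abort_eeg("`size` must be a positive integer.",
              class = "eegworkload_error_config")
  }
  candidates <- sort(unique(candidates))
  if (size > length(candidates)) {
    abort_eeg(sprintf("`size` (%d) exceeds the %d candidates.",
                      size, length(candidates)),
              class = "eegworkload_error_config")
  }
  sets <- combn(candidates, size, simplify = FALSE)
  tibble(combo = vapply(sets, paste, "", collapse = "+"),
         channels = sets)
}

#' Evaluate channel combinations with a leave-one-subject-out model
#'
#' Restricts the indicator's feature matrix to each combination's channels,
#' runs the LOSO evaluation, and summarises per-combination stability
#' (minimum and mean held-out accuracy, number of subjects at perfect
#' accuracy).
#'
#' @param combos A tibble from [enumerate_combinations()] (or a list of
#'   label vectors).
#' @param ind A single-indicator `indicator_tbl` covering all subjects.
#' @param scheme A label scheme (see [label_scheme()]) mapping conditions to
#'   classes; default the 4-class scheme.
#' @param cfg A [model_config()].
#' @return A tibble of class `combination_result`, sorted by decreasing
#'   minimum then mean accuracy: `combo`, `size`, `min_accuracy`,
#'   `mean_accuracy`, `n_perfect`, `report` (list of per-subject LOSO
#'   reports).
#' @export
evaluate_combinations <- function(combos, ind,
                                  scheme = label_scheme("zero_low_med_high"),
                                  cfg = model_config()) {
  if (is.list(combos) && !is.data.frame(combos)) {
    combos <- tibble(combo = vapply(combos, paste, "", collapse = "+"),
                     channels = lapply(combos, identity))
  }
  if (nrow(combos) == 0) {
    abort_eeg("`combos` must be non-empty.", class = "eegworkload_error_config")
  }
  im <- indicator_matrix(ind)
  available <- colnames(im$values)
  labelled <- apply_label_scheme(im$info, scheme)
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    chans <- combos$channels[[i]]
    unknown <- setdiff(chans, available)
    if (length(unknown) > 0) {
      abort_eeg(sprintf("Unknown channel label(s): %s",
                        paste(unknown, collapse = ", ")),
                class = "eegworkload_error_channel")
    }
    rep <- loso_evaluate(im$values[, chans, drop = FALSE],
                         labelled$class, labelled$subject, cfg)
    tibble(combo = combos$combo[i],
           size = length(chans),
           min_accuracy = min(rep$accuracy),
           mean_accuracy = mean(rep$accuracy),
           n_perfect = sum(rep$accuracy >= 1 - 1e-9),
           report = list(rep))
  })
  out <- bind_rows(rows)
  out <- arrange(out, desc(.data$min_accuracy), desc(.data$mean_accuracy),
                 .data$combo)
  attr(out, "scheme") <- scheme
  attr(out, "model_config") <- cfg
  class(out) <- c("combination_result", class(out))
  out
}
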