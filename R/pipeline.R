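#' Pipeline configuration
#'
#' Nested configuration for the end-to-end run: simulation, preprocessing,
#' spectral settings, indicator evaluation, channel selection and
#' modelling. Unknown keys are rejected. The global `seed` drives every
#' stochastic stage.
#'
#' @param simulation Named list of [sim_config()] overrides (e.g.
#'   `n_subjects`, `duration_per_condition`, `sampling_rate`).
#' @param preprocessing Named list: `low`, `high`, `notch`, `epoch_length`,
#'   `overlap`.
#' @param spectral Named list: `seg_seconds`, `seg_overlap`.
#' @param evaluation Named list: `n_bins`, `method`, `include_diagonal`.
#' @param selection Named list: `top_k`, `threshold`, `combo_sizes`,
#'   `max_candidates`.
#' @param model Named list: `classifier`, `scheme`, `grid_search`.
#' @param seed Global seed.
#' @param out_dir Output directory for [run_pipeline()].
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(simulation = list(), preprocessing = list(),
                            spectral = list(), evaluation = list(),
                            selection = list(), model = list(),
                            seed = 1L, out_dir = tempfile("eegworkload_run_")) {
  defaults <- list(
    simulation = list(n_subjects = 5, sampling_rate = 250,
                      duration_per_condition = 180, noise_exponent = 1,
                      subject_gain_sd = 0.2),
    preprocessing = list(low = 0.5, high = 80, notch = 50,
                         epoch_length = 2, overlap = 0),
    spectral = list(seg_seconds = 1, seg_overlap = 0.5),
    evaluation = list(n_bins = 10, method = "equal_frequency",
                      include_diagonal = TRUE),
    selection = list(top_k = 10, threshold = 0.8, combo_sizes = c(1, 2, 3),
                     max_candidates = 6),
    model = list(classifier = "decision_tree", scheme = "zero_low_med_high",
                 grid_search = FALSE)
  )
  supplied <- list(simulation = simulation, preprocessing = preprocessing,
                   spectral = spectral, evaluation = evaluation,
                   selection = selection, model = model)
  sim_allowed <- names(formals(sim_config))
  for (section in names(supplied)) {
    allowed <- if (section == "simulation") sim_allowed
               else names(defaults[[section]])
    unknown <- setdiff(names(supplied[[section]]), allowed)
    if (length(unknown) > 0) {
      abort_eeg(sprintf("Unknown key(s) in config section '%s': %s",
                        section, paste(unknown, collapse = ", ")),
                class = "eegworkload_error_schema")
    }
  }
  cfg <- lapply(names(defaults), function(section) {
    modifyList(defaults[[section]], supplied[[section]])
  })
  names(cfg) <- names(defaults)
  cfg$seed <- as.integer(seed)
  cfg$out_dir <- out_dir
  structure(cfg, class = "pipeline_config")
}

#' Read / write a pipeline configuration as JSON
#'
#' @param path JSON file path.
#' @param config A `pipeline_config`.
#' @return `read_pipeline_config()` returns a validated `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- c("simulation", "preprocessing", "spectral", "evaluation",
             "selection", "model", "seed", "out_dir")
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    abort_eeg(sprintf("Unknown top-level config key(s): %s",
                      paste(unknown, collapse = ", ")),
              class = "eegworkload_error_schema")
  }
  do.call(pipeline_config, raw)
}

#' @rdname read_pipeline_config
#' @export
write_pipeline_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

write_tsv_artifact <- function(x, path) {
  df <- as.data.frame(x)
  df <- df[, !vapply(df, is.list, TRUE), drop = FALSE]
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], function(v) formatC(v, digits = 15, format = "g"))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full synthetic-to-model pipeline
#'
#' Executes simulate -> preprocess -> band powers -> indicators ->
#' indicator evaluation -> per-subject mRMR channel ranking -> frequency
#' aggregation -> combination enumeration and LOSO evaluation, writing all
#' stage artifacts (TSV/JSON) and an MD5 manifest into the run directory.
#' Reruns with the same configuration and seed reproduce identical
#' artifacts.
#'
#' @param config A [pipeline_config()].
#' @param quiet Suppress stage progress messages.
#' @return Invisibly, a list with the run directory, the stage outputs
#'   (`evaluation`, `frequency`, `combinations`, `best_report`) and the
#'   manifest of artifact hashes.
#' @export
run_pipeline <- function(config = pipeline_config(), quiet = FALSE) {
  if (!inherits(config, "pipeline_config")) {
    abort_eeg("`config` must be a pipeline_config().",
              class = "eegworkload_error_schema")
  }
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(fmt, ...) if (!quiet) message(sprintf(fmt, ...))
  stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- tryCatch(expr, error = function(e) {
      abort_eeg(sprintf("Stage '%s' failed: %s", name, conditionMessage(e)),
                class = "eegworkload_error_stage")
    })
    say("[%s] done in %.1f s", name, as.numeric(Sys.time() - t0, units = "secs"))
    res
  }
  artifacts <- character(0)
  keep <- function(path) { artifacts <<- c(artifacts, path); path }

  # out_dir is run metadata, not run content: keep it out of the hashed config
  cfg_content <- config
  cfg_content$out_dir <- NULL
  keep(write_pipeline_config(cfg_content, file.path(out_dir, "run_config.json")))

  sim_cfg <- do.call(sim_config, c(config$simulation,
                                   list(seed = config$seed)))
  cohort <- stage("simulate", simulate_cohort(sim_cfg))
  for (s in cohort) {
    keep(write_manifest(s$manifest,
                        file.path(out_dir,
                                  sprintf("manifest_%s.json",
                                          s$manifest$subject_id))))
  }

  pp <- config$preprocessing
  bp_all <- stage("preprocess+features", {
    parts <- lapply(cohort, function(s) {
      rec <- prune_channels(s$recording, sim_cfg$utility_channels)
      rec <- rereference_average(rec)
      rec <- bandpass_filter(rec, pp$low, pp$high, pp$notch)
      ep <- segment_epochs(rec, pp$epoch_length, pp$overlap)
      band_powers(ep, seg_seconds = config$spectral$seg_seconds,
                  seg_overlap = config$spectral$seg_overlap)
    })
    bind_rows(parts)
  })

  ind <- stage("indicators", compute_indicators(bp_all))
  eval_cfg <- evaluation_config(
    scheme = discretization_scheme(config$evaluation$method,
                                   config$evaluation$n_bins),
    include_diagonal = config$evaluation$include_diagonal)
  evaluation <- stage("evaluate-indicators",
                      evaluate_indicators(ind, cfg = eval_cfg))
  keep(write_tsv_artifact(evaluation, file.path(out_dir, "evaluation.tsv")))

  top_id <- evaluation$indicator_id[1]
  ind_top <- ind[ind$indicator_id == top_id, ]
  class(ind_top) <- class(ind)
  say("top indicator: %d (%s)", top_id, evaluation$name[1])

  sel <- config$selection
  rankings <- stage("select-channels", {
    lapply(unique(ind_top$subject), function(sub) {
      sub_tbl <- ind_top[ind_top$subject == sub, ]
      class(sub_tbl) <- class(ind_top)
      greedy_mrmr_channels(sub_tbl, k = min(sel$top_k,
                                            length(unique(sub_tbl$channel))),
                           cfg = eval_cfg)
    })
  })
  rank_tbl <- bind_rows(lapply(rankings, function(r) {
    mutate(as_tibble(r), subject = attr(r, "subject"), .before = 1)
  }))
  keep(write_tsv_artifact(rank_tbl, file.path(out_dir, "channel_rankings.tsv")))

  freq <- aggregate_frequency(rankings, top_k = sel$top_k,
                              threshold = sel$threshold)
  keep(write_tsv_artifact(freq, file.path(out_dir, "channel_frequency.tsv")))
  candidates <- freq$channel[freq$candidate]
  if (length(candidates) < max(sel$combo_sizes)) {
    say("only %d channels reach the %.0f%% threshold; topping up to %d by frequency",
        length(candidates), 100 * sel$threshold, max(sel$combo_sizes))
    candidates <- head(freq$channel, max(max(sel$combo_sizes),
                                         length(candidates)))
  }
  candidates <- head(candidates, sel$max_candidates)

  scheme <- label_scheme(config$model$scheme)
  model_cfg <- if (isTRUE(config$model$grid_search)) {
    model_config(config$model$classifier, seed = config$seed)
  } else {
    grid <- if (config$model$classifier == "decision_tree") {
      data.frame(max_depth = 10, min_leaf = 5, split = "gini")
    } else {
      data.frame(cost = 1, gamma = NA)
    }
    model_config(config$model$classifier, grid = grid, seed = config$seed)
  }
  combo_results <- stage("evaluate-combinations", {
    bind_rows(lapply(sel$combo_sizes, function(sz) {
      combos <- enumerate_combinations(candidates, sz)
      evaluate_combinations(combos, ind_top, scheme, model_cfg)
    }))
  })
  keep(write_tsv_artifact(combo_results,
                          file.path(out_dir, "combination_results.tsv")))

  best <- combo_results[combo_results$size == max(combo_results$size), ][1, ]
  best_report <- best$report[[1]]
  keep(write_tsv_artifact(best_report, file.path(out_dir, "best_model_report.tsv")))

  summary <- list(
    top_indicator_id = top_id,
    top_indicator_name = evaluation$name[1],
    top_phi_bits = evaluation$phi[1],
    candidates = candidates,
    best_combo = best$combo,
    best_combo_min_accuracy = best$min_accuracy,
    best_combo_mean_accuracy = best$mean_accuracy,
    n_subjects = sim_cfg$n_subjects,
    n_epochs = length(unique(ind$epoch)),
    seed = config$seed
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  keep(file.path(out_dir, "summary.json"))

  hashes <- tools::md5sum(sort(unique(artifacts)))
  manifest <- tibble(file = basename(names(hashes)), md5 = unname(hashes))
  write_tsv_artifact(manifest, file.path(out_dir, "artifact_manifest.tsv"))

  invisible(list(out_dir = out_dir, evaluation = evaluation,
                 frequency = freq, combinations = combo_results,
                 best_report = best_report, manifest = manifest))
}
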