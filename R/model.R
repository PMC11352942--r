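#' Classifier configuration for workload detection
#'
#' Few-channel workload classification uses a depth-limited decision tree
#' (default) or an RBF support-vector machine, with hyperparameters chosen
#' per fold by grid search on an inner leave-one-subject-out loop.
#'
#' The default tree grid crosses depth (3, 5, 7, 10), minimum leaf size
#' (1, 5, 10) and split criterion (gini, information); the default SVM grid
#' crosses cost (0.1, 1, 10) with kernel width (library default, 0.01,
#' 0.1). Pass a single-row `grid` to skip the inner search (e.g. the fixed
#' depth-10 tree).
#'
#' @param classifier `"decision_tree"` or `"svm"`.
#' @param max_depth Cap on tree depth (default 10).
#' @param grid Optional data frame of hyperparameter rows; `NULL` selects
#'   the default grid for the classifier.
#' @param seed Seed driving any stochastic fitting step.
#' @return A list of class `model_config`.
#' @export
model_config <- function(classifier = c("decision_tree", "svm"),
                         max_depth = 10, grid = NULL, seed = 1L) {
  classifier <- match.arg(classifier)
  if (!is_scalar_number(max_depth) || max_depth < 1) {
    abort_eeg("`max_depth` must be >= 1.", class = "eegworkload_error_config")
  }
  if (is.null(grid)) {
    grid <- if (classifier == "decision_tree") {
      expand.grid(max_depth = pmin(c(3, 5, 7, 10), max_depth),
                  min_leaf = c(1, 5, 10),
                  split = c("gini", "information"),
                  stringsAsFactors = FALSE)
    } else {
      expand.grid(cost = c(0.1, 1, 10), gamma = c(NA, 0.01, 0.1))
    }
    grid <- unique(grid)
  }
  grid <- as.data.frame(grid)
  if (nrow(grid) == 0) {
    abort_eeg("`grid` must have at least one row.",
              class = "eegworkload_error_config")
  }
  structure(list(classifier = classifier, max_depth = max_depth,
                 grid = grid, seed = as.integer(seed)),
            class = "model_config")
}

fit_classifier <- function(X, y, params, cfg) {
  y <- droplevels(y)
  if (cfg$classifier == "decision_tree") {
    df <- data.frame(X, check.names = FALSE)
    df$.class <- y
    fit <- rpart::rpart(
      .class ~ ., data = df, method = "class",
      parms = list(split = params$split %||% "gini"),
      control = rpart::rpart.control(
        maxdepth = params$max_depth %||% cfg$max_depth,
        minbucket = params$min_leaf %||% 5,
        minsplit = max(2, 2 * (params$min_leaf %||% 5)),
        cp = 0, xval = 0, maxcompete = 0, maxsurrogate = 0))
  } else {
    scale_cols <- apply(X, 2, sd) > 0
    args <- list(x = X, y = y, kernel = "radial",
                 cost = params$cost %||% 1, probability = TRUE,
                 scale = scale_cols)
    if (!is.null(params$gamma) && !is.na(params$gamma)) {
      args$gamma <- params$gamma
    }
    fit <- do.call(e1071::svm, args)
  }
  list(fit = fit, classifier = cfg$classifier, classes = levels(y))
}

predict_classifier <- function(model, X, class_levels) {
  if (model$classifier == "decision_tree") {
    df <- data.frame(X, check.names = FALSE)
    prob_raw <- predict(model$fit, df, type = "prob")
    pred_raw <- colnames(prob_raw)[max.col(prob_raw, ties.method = "first")]
  } else {
    pr <- predict(model$fit, X, probability = TRUE)
    prob_raw <- attr(pr, "probabilities")
    pred_raw <- as.character(pr)
  }
  prob <- matrix(0, nrow(X), length(class_levels),
                 dimnames = list(NULL, class_levels))
  common <- intersect(colnames(prob_raw), class_levels)
  prob[, common] <- prob_raw[, common, drop = FALSE]
  list(class = factor(pred_raw, levels = class_levels), prob = prob)
}

# accuracy + macro precision/recall/F1 + macro one-vs-rest ROC AUC
classification_metrics <- function(truth, pred, prob, class_levels) {
  truth <- factor(truth, levels = class_levels)
  pred <- factor(pred, levels = class_levels)
  acc <- mean(pred == truth)
  present <- class_levels[table(truth)[class_levels] > 0]
  prec <- rec <- f1 <- numeric(0)
  for (cl in present) {
    tp <- sum(pred == cl & truth == cl)
    fp <- sum(pred == cl & truth != cl)
    fn <- sum(pred != cl & truth == cl)
    p <- if (tp + fp > 0) tp / (tp + fp) else 0
    r <- if (tp + fn > 0) tp / (tp + fn) else 0
    prec <- c(prec, p); rec <- c(rec, r)
    f1 <- c(f1, if (p + r > 0) 2 * p * r / (p + r) else 0)
  }
  aucs <- numeric(0)
  for (cl in present) {
    pos <- as.integer(truth == cl)
    if (sum(pos) > 0 && sum(pos) < length(pos) && sd(prob[, cl]) >= 0) {
      a <- tryCatch(
        as.numeric(pROC::auc(pROC::roc(pos, prob[, cl], levels = c(0, 1),
                                       direction = "<", quiet = TRUE))),
        error = function(e) NA_real_)
      if (!is.na(a)) aucs <- c(aucs, a)
    }
  }
  list(accuracy = acc,
       precision = mean(prec), recall = mean(rec), f1 = mean(f1),
       auc = if (length(aucs) > 0) mean(aucs) else NA_real_)
}

check_folds <- function(labels, subjects) {
  class_levels <- levels(labels)
  overall <- class_levels[table(labels)[class_levels] > 0]
  for (s in unique(subjects)) {
    train_classes <- unique(as.character(labels[subjects != s]))
    missing <- setdiff(overall, train_classes)
    if (length(missing) > 0) {
      abort_eeg(sprintf(
        "Class '%s' is absent from the training data of fold '%s'.",
        missing[1], s), class = "eegworkload_error_fold")
    }
  }
}

# mean inner-LOSO accuracy of one hyperparameter row on the training block
inner_grid_accuracy <- function(X, y, subj, params, cfg, seed) {
  inner <- unique(subj)
  accs <- vapply(seq_along(inner), function(i) {
    s <- inner[i]
    tr <- subj != s
    if (length(unique(as.character(y[tr]))) < 2) return(NA_real_)
    set.seed(derive_seed(seed, i))
    m <- fit_classifier(X[tr, , drop = FALSE], y[tr], params, cfg)
    pr <- predict_classifier(m, X[!tr, , drop = FALSE], levels(y))
    mean(pr$class == y[!tr])
  }, 0)
  mean(accs, na.rm = TRUE)
}

#' Leave-one-subject-out evaluation
#'
#' Each subject's epochs form one held-out fold; the classifier is fitted
#' on all other subjects (with hyperparameters selected by an inner
#' leave-one-subject-out grid search whenever the grid has several rows and
#' at least three subjects are available) and scored on the held-out
#' subject: accuracy, macro precision/recall/F1 and macro one-vs-rest ROC
#' AUC. Deterministic for a fixed `cfg$seed`.
#'
#' @param features Epochs x features numeric matrix (or data frame); for
#'   few-channel detection, the best indicator's values on the selected
#'   channels.
#' @param labels Per-epoch class labels (factor or vector).
#' @param subjects Per-epoch subject identifiers (>= 2 distinct).
#' @param cfg A [model_config()].
#' @return A tibble of class `loso_report`, one row per held-out subject:
#'   `subject`, `n_test`, `accuracy`, `precision`, `recall`, `f1`, `auc`,
#'   `params` (list of the hyperparameters chosen for that fold).
#' @export
loso_evaluate <- function(features, labels, subjects, cfg = model_config()) {
  X <- as.matrix(features)
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  y <- if (is.factor(labels)) labels else factor(labels)
  subjects <- as.character(subjects)
  if (nrow(X) != length(y) || nrow(X) != length(subjects)) {
    abort_eeg("features, labels and subjects must align row-wise.",
              class = "eegworkload_error_config")
  }
  subj_ids <- unique(subjects)
  if (length(subj_ids) < 2) {
    abort_eeg("LOSO evaluation needs at least 2 subjects.",
              class = "eegworkload_error_config")
  }
  check_folds(y, subjects)
  class_levels <- levels(y)
  grid <- cfg$grid
  rows <- vector("list", length(subj_ids))
  preds <- vector("list", length(subj_ids))
  for (i in seq_along(subj_ids)) {
    s <- subj_ids[i]
    tr <- subjects != s
    Xtr <- X[tr, , drop = FALSE]; ytr <- droplevels(y[tr])
    params <- as.list(grid[1, , drop = FALSE])
    if (nrow(grid) > 1 && length(unique(subjects[tr])) >= 2) {
      scores <- vapply(seq_len(nrow(grid)), function(g) {
        inner_grid_accuracy(Xtr, ytr, subjects[tr],
                            as.list(grid[g, , drop = FALSE]), cfg,
                            derive_seed(cfg$seed, 1000 * i + g))
      }, 0)
      params <- as.list(grid[which.max(scores), , drop = FALSE])
    }
    set.seed(derive_seed(cfg$seed, i))
    m <- fit_classifier(Xtr, ytr, params, cfg)
    pr <- predict_classifier(m, X[!tr, , drop = FALSE], class_levels)
    met <- classification_metrics(y[!tr], pr$class, pr$prob, class_levels)
    rows[[i]] <- tibble(subject = s, n_test = sum(!tr),
                        accuracy = met$accuracy, precision = met$precision,
                        recall = met$recall, f1 = met$f1, auc = met$auc,
                        params = list(params))
    preds[[i]] <- tibble(subject = s, row = which(!tr),
                         truth = y[!tr], predicted = pr$class)
  }
  out <- bind_rows(rows)
  attr(out, "predictions") <- bind_rows(preds)
  attr(out, "config") <- cfg
  attr(out, "class_levels") <- class_levels
  class(out) <- c("loso_report", class(out))
  out
}

#' Fit a workload detection model on a full cohort
#'
#' Grid-searches hyperparameters by leave-one-subject-out on the cohort
#' (when `subjects` is given and the grid has several rows), then fits the
#' final classifier on all epochs.
#'
#' @inheritParams loso_evaluate
#' @param subjects Optional per-epoch subject ids used for the inner grid
#'   search.
#' @return An object of class `workload_model`.
#' @export
fit_workload_model <- function(features, labels, subjects = NULL,
                               cfg = model_config()) {
  X <- as.matrix(features)
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  y <- if (is.factor(labels)) labels else factor(labels)
  params <- as.list(cfg$grid[1, , drop = FALSE])
  if (nrow(cfg$grid) > 1 && !is.null(subjects) &&
      length(unique(subjects)) >= 2) {
    scores <- vapply(seq_len(nrow(cfg$grid)), function(g) {
      inner_grid_accuracy(X, y, as.character(subjects),
                          as.list(cfg$grid[g, , drop = FALSE]), cfg,
                          derive_seed(cfg$seed, 5000 + g))
    }, 0)
    params <- as.list(cfg$grid[which.max(scores), , drop = FALSE])
  }
  set.seed(derive_seed(cfg$seed, 0))
  m <- fit_classifier(X, y, params, cfg)
  structure(list(fit = m, params = params, cfg = cfg,
                 feature_names = colnames(X), class_levels = levels(y)),
            class = "workload_model")
}

#' @export
print.workload_model <- function(x, ...) {
  cat(sprintf("<workload_model> %s on %d feature(s): %s\n",
              x$cfg$classifier, length(x$feature_names),
              paste(x$feature_names, collapse = ", ")))
  cat("classes:", paste(x$class_levels, collapse = " < "), "\n")
  invisible(x)
}

#' Validate a fitted model on a new cohort without refitting
#'
#' @param model A `workload_model` from [fit_workload_model()].
#' @param features New epochs x features matrix; column names must match
#'   the model's feature names (same indicator, channels and preprocessing).
#' @param labels Per-epoch class labels of the new cohort.
#' @param subjects Optional per-epoch subject ids; metrics are reported per
#'   subject when given, pooled otherwise.
#' @return A tibble of class `holdout_report` with the same metric columns
#'   as [loso_evaluate()].
#' @export
holdout_validate <- function(model, features, labels, subjects = NULL) {
  X <- as.matrix(features)
  if (is.null(colnames(X)) ||
      !identical(sort(colnames(X)), sort(model$feature_names))) {
    abort_eeg(sprintf(
      "Feature/channel mismatch: model expects {%s}, data has {%s}.",
      paste(model$feature_names, collapse = ", "),
      paste(colnames(X) %||% "<unnamed>", collapse = ", ")),
      class = "eegworkload_error_channel")
  }
  X <- X[, model$feature_names, drop = FALSE]
  y <- factor(labels, levels = model$class_levels)
  if (anyNA(y)) {
    abort_eeg("New labels contain classes unknown to the model.",
              class = "eegworkload_error_config")
  }
  groups <- if (is.null(subjects)) rep("all", nrow(X)) else as.character(subjects)
  pr <- predict_classifier(model$fit, X, model$class_levels)
  rows <- lapply(unique(groups), function(g) {
    sel <- groups == g
    met <- classification_metrics(y[sel], pr$class[sel],
                                  pr$prob[sel, , drop = FALSE],
                                  model$class_levels)
    tibble(subject = g, n_test = sum(sel), accuracy = met$accuracy,
           precision = met$precision, recall = met$recall, f1 = met$f1,
           auc = met$auc)
  })
  out <- bind_rows(rows)
  class(out) <- c("holdout_report", class(out))
  out
}

#' SVM separability screen of the indicator catalogue
#'
#' Classifies every indicator's channel feature matrix under each labelling
#' scheme with a leave-one-subject-out SVM and reports the mean held-out
#' accuracy, giving a separability-based indicator ranking to compare with
#' the mutual-information-based one.
#'
#' @param ind An `indicator_tbl` with all indicators of interest.
#' @param schemes List of [label_scheme()] objects; default all four
#'   built-ins.
#' @param cfg A [model_config()]; default a fixed-parameter RBF SVM (no
#'   grid search), keeping the 26 x 4 screen tractable.
#' @return A tibble of class `separability_tbl`: `indicator_id` plus one
#'   accuracy column per scheme.
#' @export
svm_separability <- function(ind, schemes = NULL,
                             cfg = model_config("svm",
                                                grid = data.frame(cost = 1,
                                                                  gamma = NA))) {
  if (is.null(schemes)) {
    schemes <- lapply(c("resting_working", "zero_lowmed_high",
                        "zero_low_medhigh", "zero_low_med_high"),
                      label_scheme)
  }
  ids <- sort(unique(ind$indicator_id))
  out <- tibble(indicator_id = ids)
  for (sch in schemes) {
    nm <- attr(sch, "scheme_name")
    acc <- vapply(ids, function(id) {
      im <- indicator_matrix(ind, id)
      lab <- apply_label_scheme(im$info, sch)
      rep_tbl <- loso_evaluate(im$values, lab$class, lab$subject, cfg)
      mean(rep_tbl$accuracy)
    }, 0)
    out[[nm]] <- acc
  }
  class(out) <- c("separability_tbl", class(out))
  out
}

#' Agreement between the Phi ranking and the SVM separability ranking
#'
#' Min-max normalises each scheme's accuracy column, averages the
#' normalised accuracies across schemes per indicator, and reports the
#' Spearman rank correlation between that consensus score and the
#' evaluation statistic `phi`.
#'
#' @param evaluation An `indicator_evaluation` from [evaluate_indicators()].
#' @param separability A `separability_tbl` from [svm_separability()]
#'   covering the same indicator ids.
#' @return A list of class `consensus_report`: `spearman_rho` and `table`
#'   (per-indicator phi, phi rank, mean normalised accuracy and its rank).
#' @export
cross_indicator_consensus <- function(evaluation, separability) {
  ids_a <- sort(evaluation$indicator_id)
  ids_b <- sort(separability$indicator_id)
  if (!identical(ids_a, ids_b)) {
    abort_eeg("Evaluation and separability cover different indicator ids.",
              class = "eegworkload_error_config")
  }
  scheme_cols <- setdiff(names(separability), "indicator_id")
  norm_cols <- list()
  for (sc in scheme_cols) {
    v <- separability[[sc]]
    if (max(v) > min(v)) {
      norm_cols[[sc]] <- minmax_normalize(v)
    } else {
      warning(sprintf("Scheme '%s' has constant accuracy; dropped from the consensus mean.", sc),
              call. = FALSE)
    }
  }
  if (length(norm_cols) == 0) {
    abort_eeg("No scheme has non-constant accuracy; consensus undefined.",
              class = "eegworkload_error_degenerate")
  }
  mean_norm <- rowMeans(do.call(cbind, norm_cols))
  tbl <- tibble(indicator_id = separability$indicator_id,
                mean_norm_accuracy = mean_norm)
  tbl <- left_join(tbl,
                   evaluation[c("indicator_id", "phi", "rank")],
                   by = "indicator_id")
  tbl <- rename(tbl, phi_rank = "rank")
  tbl$accuracy_rank <- rank(-tbl$mean_norm_accuracy, ties.method = "average")
  rho <- cor(tbl$phi, tbl$mean_norm_accuracy, method = "spearman")
  structure(list(spearman_rho = rho, table = tbl),
            class = "consensus_report")
}

#' @export
print.consensus_report <- function(x, ...) {
  cat(sprintf("<consensus_report> Spearman rho = %.3f over %d indicators\n",
              x$spearman_rho, nrow(x$table)))
  invisible(x)
}
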