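# separable multi-subject features: class recoverable from feature 1 with a
# margin, consistently across subjects
separable_cohort <- function(n_subjects = 3, per_class = 12, n_classes = 4,
                             seed = 31) {
  withr::with_seed(seed, {
    grid <- expand.grid(subject = sprintf("s%d", seq_len(n_subjects)),
                        class = LETTERS[seq_len(n_classes)],
                        i = seq_len(per_class), stringsAsFactors = FALSE)
    x1 <- as.integer(factor(grid$class)) + runif(nrow(grid), -0.3, 0.3)
    x2 <- rnorm(nrow(grid))
    list(features = cbind(f1 = x1, f2 = x2),
         labels = factor(grid$class),
         subjects = grid$subject)
  })
}

test_that("label schemes partition the five conditions as specified", {
  rw <- label_scheme("resting_working")
  expect_equal(as.character(rw$class),
               c("resting", rep("working", 4)))
  four <- label_scheme("zero_low_med_high")
  expect_equal(levels(four$class), c("zero", "low", "medium", "high"))
  expect_equal(as.character(four$class[four$condition %in%
                                         c("scenario3", "scenario4")]),
               c("high", "high"))
  expect_equal(nlevels(label_scheme("zero_lowmed_high")$class), 3)
  expect_error(label_scheme("custom", mapping = c(rest = "a")),
               "scenario1", class = "eegworkload_error_config")
  # applying a scheme attaches classes; unknown conditions are named
  df <- tibble::tibble(condition = c("rest", "scenario9"))
  expect_error(apply_label_scheme(df, four), "scenario9",
               class = "eegworkload_error_config")
  ok <- apply_label_scheme(tibble::tibble(condition = c("rest", "scenario2")),
                           four)
  expect_equal(as.character(ok$class), c("zero", "medium"))
})

test_that("LOSO produces one fold per subject and nails separable data", {
  coh <- separable_cohort(n_subjects = 4)
  cfg <- model_config(grid = data.frame(max_depth = 10, min_leaf = 1,
                                        split = "gini"))
  rep_tbl <- loso_evaluate(coh$features, coh$labels, coh$subjects, cfg)
  expect_equal(nrow(rep_tbl), 4)
  expect_equal(rep_tbl$subject, sprintf("s%d", 1:4))
  expect_true(all(rep_tbl$accuracy == 1))
  expect_true(all(rep_tbl$f1 == 1))
  expect_true(all(rep_tbl$auc == 1))
})

test_that("a class missing from a training fold raises a named error", {
  coh <- separable_cohort(n_subjects = 2, n_classes = 2)
  # class B occurs only in subject s2: training for fold s2 lacks it
  labels <- coh$labels
  labels[coh$subjects == "s1" & labels == "B"] <- "A"
  expect_error(loso_evaluate(coh$features, labels, coh$subjects,
                             model_config(grid = data.frame(max_depth = 3,
                                                            min_leaf = 1,
                                                            split = "gini"))),
               "s2", class = "eegworkload_error_fold")
})

test_that("reported metrics obey their definitions", {
  truth <- factor(c("a", "a", "a", "b", "b", "c"), levels = c("a", "b", "c"))
  pred <- factor(c("a", "b", "a", "b", "a", "c"), levels = c("a", "b", "c"))
  prob <- matrix(1 / 3, 6, 3, dimnames = list(NULL, c("a", "b", "c")))
  met <- eegworkload:::classification_metrics(truth, pred, prob,
                                              c("a", "b", "c"))
  expect_equal(met$accuracy, mean(pred == truth))
  # brute-force macro precision/recall/F1
  per <- lapply(c("a", "b", "c"), function(cl) {
    tp <- sum(pred == cl & truth == cl)
    fp <- sum(pred == cl & truth != cl)
    fn <- sum(pred != cl & truth == cl)
    p <- if (tp + fp > 0) tp / (tp + fp) else 0
    r <- if (tp + fn > 0) tp / (tp + fn) else 0
    c(p = p, r = r, f = if (p + r > 0) 2 * p * r / (p + r) else 0)
  })
  expect_equal(met$precision, mean(vapply(per, `[[`, 0, "p")))
  expect_equal(met$recall, mean(vapply(per, `[[`, 0, "r")))
  expect_equal(met$f1, mean(vapply(per, `[[`, 0, "f")))
})

test_that("fold models never see held-out labels", {
  coh <- separable_cohort(n_subjects = 3)
  cfg <- model_config(grid = data.frame(max_depth = 5, min_leaf = 1,
                                        split = "gini"))
  rep1 <- loso_evaluate(coh$features, coh$labels, coh$subjects, cfg)
  # permute subject s1's labels: fold s1's *predictions* must not move
  labels2 <- coh$labels
  sel <- coh$subjects == "s1"
  labels2[sel] <- sample(labels2[sel])
  rep2 <- loso_evaluate(coh$features, labels2, coh$subjects, cfg)
  p1 <- attr(rep1, "predictions")
  p2 <- attr(rep2, "predictions")
  expect_identical(p1$predicted[p1$subject == "s1"],
                   p2$predicted[p2$subject == "s1"])
})

test_that("LOSO with a fixed seed is fully reproducible (SVM path)", {
  coh <- separable_cohort(n_subjects = 3, per_class = 8, n_classes = 3)
  cfg <- model_config("svm", seed = 7)
  r1 <- loso_evaluate(coh$features, coh$labels, coh$subjects, cfg)
  r2 <- loso_evaluate(coh$features, coh$labels, coh$subjects, cfg)
  expect_identical(r1$accuracy, r2$accuracy)
  expect_identical(r1$auc, r2$auc)
  expect_identical(r1$params, r2$params)
})

test_that("constant features predict the majority class", {
  labels <- factor(rep(c("maj", "maj", "maj", "min"), 10))
  subjects <- rep(c("s1", "s2"), each = 20)
  X <- matrix(1, 40, 2, dimnames = list(NULL, c("f1", "f2")))
  cfg <- model_config(grid = data.frame(max_depth = 3, min_leaf = 1,
                                        split = "gini"))
  rep_tbl <- loso_evaluate(X, labels, subjects, cfg)
  expect_equal(rep_tbl$accuracy, rep(0.75, 2))
})

test_that("the SVM separability screen is shaped indicators x schemes", {
  cfg <- tiny_sim_config(n_subjects = 2, duration = 24, seed = 33,
                         channel_labels = c("CP2", "CP5", "TP7", "Cz", "VEO"),
                         utility_channels = "VEO",
                         informative_channels = c("CP2", "CP5", "TP7"),
                         band_effect = list(gamma = 3^(0:4)))
  cohort <- simulate_cohort(cfg)
  bp <- dplyr::bind_rows(lapply(cohort, function(s) {
    band_powers(segment_epochs(prune_channels(s$recording, "VEO"), 2))
  }))
  ind <- compute_indicators(bp)
  sep <- svm_separability(ind)
  expect_equal(nrow(sep), 26)
  expect_equal(ncol(sep), 5)  # indicator_id + 4 schemes
  expect_true(all(unlist(sep[-1]) >= 0 & unlist(sep[-1]) <= 1))
  # strong gamma modulation: gamma-bearing indicators separate rest/work well
  expect_gt(max(sep$resting_working[sep$indicator_id %in% 14:16]), 0.8)
})

test_that("consensus reporting recovers perfect and reversed agreement", {
  ev <- tibble::tibble(indicator_id = 1:6, phi = c(6, 5, 4, 3, 2, 1),
                       rank = 1:6)
  class(ev) <- c("indicator_evaluation", class(ev))
  agree <- tibble::tibble(indicator_id = 1:6,
                          s1 = c(0.9, 0.8, 0.7, 0.6, 0.5, 0.4),
                          s2 = c(0.95, 0.85, 0.8, 0.7, 0.6, 0.5))
  class(agree) <- c("separability_tbl", class(agree))
  expect_equal(cross_indicator_consensus(ev, agree)$spearman_rho, 1)
  disagree <- agree
  disagree$s1 <- rev(disagree$s1); disagree$s2 <- rev(disagree$s2)
  expect_equal(cross_indicator_consensus(ev, disagree)$spearman_rho, -1)
  expect_error(cross_indicator_consensus(ev, agree[1:5, ]),
               class = "eegworkload_error_config")
})

test_that("hold-out validation reuses the fitted model without refitting", {
  coh <- separable_cohort(n_subjects = 4)
  fitcfg <- model_config(grid = data.frame(max_depth = 10, min_leaf = 1,
                                           split = "gini"))
  train_sel <- coh$subjects %in% c("s1", "s2", "s3")
  model <- fit_workload_model(coh$features[train_sel, ], coh$labels[train_sel],
                              coh$subjects[train_sel], fitcfg)
  # leakage sanity: scoring a subset of the training epochs is optimistic
  inset <- holdout_validate(model, coh$features[train_sel, ],
                            coh$labels[train_sel])
  expect_gte(inset$accuracy, 1 - 1e-9)
  # a genuinely new subject from the same generator scores highly too
  new_sel <- coh$subjects == "s4"
  newrep <- holdout_validate(model, coh$features[new_sel, ],
                             coh$labels[new_sel], coh$subjects[new_sel])
  expect_gte(newrep$accuracy, 0.9)
  # renamed channels are rejected
  bad <- coh$features[new_sel, ]
  colnames(bad) <- c("g1", "g2")
  expect_error(holdout_validate(model, bad, coh$labels[new_sel]),
               class = "eegworkload_error_channel")
})

test_that("tidiers summarise reports", {
  coh <- separable_cohort(n_subjects = 3)
  cfg <- model_config(grid = data.frame(max_depth = 5, min_leaf = 1,
                                        split = "gini"))
  rep_tbl <- loso_evaluate(coh$features, coh$labels, coh$subjects, cfg)
  td <- tidy(rep_tbl)
  expect_false("params" %in% names(td))
  gl <- glance(rep_tbl)
  expect_equal(gl$n_subjects, 3)
  expect_equal(gl$mean_accuracy, mean(rep_tbl$accuracy))
})
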