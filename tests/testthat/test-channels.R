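fake_ranking <- function(channels_top, all_channels, subject = "s") {
  out <- tibble::tibble(rank = seq_along(channels_top),
                        channel = channels_top,
                        score = rev(seq_along(channels_top)),
                        relevance = rev(seq_along(channels_top)))
  attr(out, "subject") <- subject
  attr(out, "channels") <- all_channels
  class(out) <- c("channel_ranking", class(out))
  out
}

test_that("greedy selection with k = |S| is a permutation of all channels", {
  set.seed(21)
  X <- toy_matrix(120, paste0("ch", 1:6))
  labels <- sample(0:1, 120, replace = TRUE)
  rk <- greedy_mrmr_channels(X, labels, k = 6)
  expect_setequal(rk$channel, colnames(X))
  expect_equal(rk$rank, 1:6)
  expect_error(greedy_mrmr_channels(X, labels, k = 7),
               class = "eegworkload_error_config")
})

test_that("the redundancy penalty vetoes an exact duplicate channel", {
  set.seed(22)
  n <- 400
  A <- rnorm(n)
  lab <- as.integer(A > 0)                      # A determines the label
  X <- cbind(A = A, B = A,                      # B duplicates A exactly
             C = rnorm(n), D = rnorm(n))        # uninformative noise
  rk <- greedy_mrmr_channels(X, lab, k = 2)
  expect_equal(rk$channel[1], "A")              # ties A/B break by label
  # B's incremental score is 1 - H(binned A) << 0; noise wins the 2nd slot
  expect_true(rk$channel[2] %in% c("C", "D"))
  # first pick is the exhaustive relevance argmax
  rel <- vapply(colnames(X),
                function(ch) mi_continuous_discrete(X[, ch], lab), 0)
  expect_equal(rk$channel[1], names(which.max(rel)))
})

test_that("greedy selection is deterministic and favours informative channels", {
  cfg <- tiny_sim_config(duration = 24, seed = 23)
  sim <- simulate_subject(cfg, 1)
  rec <- prune_channels(sim$recording, cfg$utility_channels)
  ind <- compute_indicators(band_powers(segment_epochs(rec, 2)), ids = 16)
  rk1 <- greedy_mrmr_channels(ind, k = 5)
  rk2 <- greedy_mrmr_channels(ind, k = 5)
  expect_identical(rk1$channel, rk2$channel)
  expect_true(rk1$channel[1] %in% cfg$informative_channels)
})

test_that("frequency aggregation counts subjects and flags candidates", {
  all_ch <- paste0("ch", 1:8)
  # identical rankings: every listed channel at frequency 1
  rks <- lapply(1:4, function(i) fake_ranking(all_ch[1:3], all_ch, i))
  fr <- aggregate_frequency(rks, top_k = 3, threshold = 0.8)
  expect_equal(fr$frequency, rep(1, 3))
  expect_true(all(fr$candidate))

  # a channel in 33 of 41 rankings: frequency 0.8049, flagged at 0.8
  rks41 <- lapply(1:41, function(i) {
    fake_ranking(if (i <= 33) c("ch1", "ch2") else c("ch3", "ch2"),
                 all_ch, i)
  })
  fr41 <- aggregate_frequency(rks41, top_k = 2, threshold = 0.8)
  expect_equal(fr41$frequency[fr41$channel == "ch1"], 33 / 41)
  expect_true(fr41$candidate[fr41$channel == "ch1"])
  expect_false(fr41$candidate[fr41$channel == "ch3"])

  # threshold 1 with disagreeing rankings: empty candidate set
  fr_hi <- aggregate_frequency(rks41, top_k = 2, threshold = 1)
  expect_equal(sum(fr_hi$candidate), 1)  # only ch2 appears everywhere
  rks_dis <- list(fake_ranking("ch1", all_ch, 1),
                  fake_ranking("ch2", all_ch, 2))
  fr_dis <- aggregate_frequency(rks_dis, top_k = 1, threshold = 1)
  expect_equal(sum(fr_dis$candidate), 0)

  # inconsistent montages are rejected
  bad <- list(fake_ranking("ch1", all_ch, 1),
              fake_ranking("ch1", paste0("zz", 1:4), 2))
  expect_error(aggregate_frequency(bad), class = "eegworkload_error_channel")
})

test_that("combination enumeration matches binomial coefficients", {
  cand <- informative_channels()
  expect_equal(nrow(enumerate_combinations(cand, 2)), 15)
  expect_equal(nrow(enumerate_combinations(cand, 3)), 20)
  expect_equal(nrow(enumerate_combinations(cand, 6)), 1)
  for (n in 2:8) {
    for (k in seq_len(n)) {
      expect_equal(nrow(enumerate_combinations(paste0("c", 1:n), k)),
                   choose(n, k))
    }
  }
  # lexicographic order, sorted tuples
  combos <- enumerate_combinations(c("TP7", "CP2", "CP5"), 2)
  expect_equal(combos$combo, c("CP2+CP5", "CP2+TP7", "CP5+TP7"))
  expect_error(enumerate_combinations(cand, 0),
               class = "eegworkload_error_config")
  expect_error(enumerate_combinations(cand, 7),
               class = "eegworkload_error_config")
})

test_that("combination evaluation restricts channels faithfully", {
  cfg <- tiny_sim_config(n_subjects = 3, duration = 16, seed = 24)
  cohort <- simulate_cohort(cfg)
  bp <- dplyr::bind_rows(lapply(cohort, function(s) {
    rec <- prune_channels(s$recording, cfg$utility_channels)
    band_powers(segment_epochs(rec, 2))
  }))
  ind <- compute_indicators(bp, ids = 16)
  mcfg <- model_config(grid = data.frame(max_depth = 10, min_leaf = 5,
                                         split = "gini"))
  scheme <- label_scheme("resting_working")
  all_ch <- sort(unique(ind$channel))
  res <- evaluate_combinations(tibble::tibble(combo = "all",
                                              channels = list(all_ch)),
                               ind, scheme, mcfg)
  im <- indicator_matrix(ind)
  lab <- apply_label_scheme(im$info, scheme)
  direct <- loso_evaluate(im$values, lab$class, lab$subject, mcfg)
  expect_equal(res$mean_accuracy, mean(direct$accuracy))
  expect_equal(res$min_accuracy, min(direct$accuracy))

  expect_error(evaluate_combinations(
    tibble::tibble(combo = "bad", channels = list(c("CP2", "NOPE"))),
    ind, scheme, mcfg), "NOPE", class = "eegworkload_error_channel")
})
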