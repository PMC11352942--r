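# test-side periodogram band power, independent of the package's Welch path
pgram_band_power <- function(x, fs, low, high) {
  n <- length(x)
  X <- stats::fft(x)
  psd <- (Mod(X)^2) / (fs * n)
  f <- (seq_len(n) - 1) * fs / n
  keep <- seq_len(floor(n / 2) + 1)
  psd <- psd[keep] * c(1, rep(2, length(keep) - 2), 1)
  f <- f[keep]
  sum(psd[f >= low & f < high]) * fs / n
}

test_that("simulated recordings have the configured montage and metadata", {
  cfg <- tiny_sim_config(n_subjects = 3)
  sim <- simulate_subject(cfg, 1)
  expect_s3_class(sim$recording, "eeg_recording")
  expect_equal(nrow(sim$recording$samples), 64)
  expect_length(sim$manifest$utility_channels, 5)
  expect_equal(sim$recording$condition_intervals$condition, cfg$conditions)
  expect_equal(unlist(sim$manifest$condition_levels),
               setNames(0:4, cfg$conditions))

  cohort <- simulate_cohort(cfg)
  expect_length(cohort, 3)
  # subjects share effect structure but differ in realised noise
  expect_identical(cohort[[1]]$manifest$band_effect,
                   cohort[[2]]$manifest$band_effect)
  expect_false(identical(cohort[[1]]$recording$samples,
                         cohort[[2]]$recording$samples))
})

test_that("simulation is deterministic for fixed config and subject", {
  cfg <- tiny_sim_config(seed = 99)
  a <- simulate_subject(cfg, 2)
  b <- simulate_subject(cfg, 2)
  expect_identical(a$recording$samples, b$recording$samples)
  expect_identical(a$manifest$subject_gains, b$manifest$subject_gains)
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(duration_per_condition = -5),
               class = "eegworkload_error_config")
  expect_error(sim_config(sampling_rate = 0),
               class = "eegworkload_error_config")
  expect_error(sim_config(utility_channels = c("VEO", "NOPE")),
               class = "eegworkload_error_config")
  expect_error(sim_config(informative_channels = c("CP2", "VEO")),
               class = "eegworkload_error_config")
  expect_error(sim_config(band_effect = list(gamma = c(1, 2, 3))),
               class = "eegworkload_error_config")
  expect_error(simulate_subject(list(), 1),
               class = "eegworkload_error_config")
})

test_that("gamma band power rises monotonically with workload on informative channels", {
  cfg <- tiny_sim_config(duration = 60, seed = 21)  # 30 epochs per level
  sim <- simulate_subject(cfg, 1)
  rec <- sim$recording
  fs <- rec$sampling_rate
  lev <- rec$condition_levels
  # the subject's most strongly modulated informative channel
  w <- unlist(sim$manifest$effect_weights)
  ch <- which(rec$channel_labels == names(which.max(w)))
  means <- vapply(cfg$conditions, function(cond) {
    iv <- rec$condition_intervals[rec$condition_intervals$condition == cond, ]
    s0 <- round(iv$start * fs)
    starts <- seq(s0, round(iv$end * fs) - 2 * fs, by = 2 * fs)
    mean(vapply(starts, function(st) {
      pgram_band_power(rec$samples[ch, (st + 1):(st + 2 * fs)], fs, 30, 45)
    }, 0))
  }, 0)
  expect_true(all(diff(means[order(lev[cfg$conditions])]) > 0))
})

test_that("without band modulation, gamma power is flat across conditions", {
  cfg <- tiny_sim_config(duration = 60, seed = 31,
                         band_effect = list(gamma = rep(1, 5)))
  rec <- simulate_subject(cfg, 1)$recording
  fs <- rec$sampling_rate
  ch <- which(rec$channel_labels == "CP2")
  per_cond <- lapply(c("rest", "scenario3"), function(cond) {
    iv <- rec$condition_intervals[rec$condition_intervals$condition == cond, ]
    starts <- seq(round(iv$start * fs), round(iv$end * fs) - 2 * fs, by = 2 * fs)
    vapply(starts, function(st) {
      pgram_band_power(rec$samples[ch, (st + 1):(st + 2 * fs)], fs, 30, 45)
    }, 0)
  })
  expect_gt(t.test(per_cond[[1]], per_cond[[2]])$p.value, 0.01)
})

test_that("background spectral slope matches the configured exponent", {
  cfg <- tiny_sim_config(duration = 40, seed = 41,
                         band_effect = list(gamma = rep(1, 5)))
  rec <- simulate_subject(cfg, 1)$recording
  fs <- rec$sampling_rate
  x <- rec$samples[which(rec$channel_labels == "Pz"), ]
  # average periodogram over 4 s windows, then log-log slope over 1-40 Hz
  L <- 4 * fs
  starts <- seq(1, length(x) - L + 1, by = L)
  psd <- rowMeans(vapply(starts, function(st) {
    Mod(stats::fft(x[st:(st + L - 1)]))[seq_len(L / 2)]^2
  }, numeric(L / 2)))
  f <- (seq_len(L / 2) - 1) * fs / L
  sel <- f >= 1 & f <= 40
  slope <- coef(lm(log(psd[sel]) ~ log(f[sel])))[2]
  expect_lt(abs(slope - (-cfg$noise_exponent)), 0.3)
})

test_that("configured band effects are recoverable from the generated data", {
  cfg <- tiny_sim_config(duration = 120, seed = 51)  # 60 epochs per level
  sim <- simulate_subject(cfg, 1)
  rec <- prune_channels(sim$recording, cfg$utility_channels)
  bp <- band_powers(segment_epochs(rec, 2))
  gm <- bp |>
    dplyr::filter(channel == "CP4") |>
    dplyr::group_by(level) |>
    dplyr::summarise(gamma = mean(gamma)) |>
    dplyr::arrange(level)
  est_ratio <- gm$gamma[-1] / gm$gamma[-5]
  # model-implied ratio, given this subject's recorded effect weight
  m <- cfg$band_effect$gamma^sim$manifest$effect_weights$CP4
  model_ratio <- (1 + cfg$osc_ratio * m[-1]^2) / (1 + cfg$osc_ratio * m[-5]^2)
  expect_true(all(abs(est_ratio / model_ratio - 1) < 0.2))
})

test_that("manifests round-trip through JSON", {
  cfg <- tiny_sim_config()
  man <- simulate_subject(cfg, 1)$manifest
  path <- withr::local_tempfile(fileext = ".json")
  write_manifest(man, path)
  back <- read_manifest(path)
  expect_equal(unlist(back$condition_levels), unlist(man$condition_levels))
  expect_equal(back$informative_channels, man$informative_channels)
  expect_equal(back$band_effect$gamma, man$band_effect$gamma)
  expect_equal(unlist(back$subject_gains), unlist(man$subject_gains),
               tolerance = 1e-12)
})
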