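# Shared fixtures: all synthetic, generated in code at test time.

# small, fast simulation config for module tests
tiny_sim_config <- function(n_subjects = 1, duration = 12, fs = 128,
                            seed = 11, ...) {
  sim_config(n_subjects = n_subjects, duration_per_condition = duration,
             sampling_rate = fs, seed = seed, ...)
}

# a small cohort processed to band powers (no filtering: the synthetic data
# is already band-limited and artifact-free, which keeps tests fast)
tiny_cohort_band_powers <- function(n_subjects = 2, duration = 12, fs = 128,
                                    seed = 11, ...) {
  cfg <- tiny_sim_config(n_subjects = n_subjects, duration = duration,
                         fs = fs, seed = seed, ...)
  parts <- lapply(simulate_cohort(cfg), function(s) {
    rec <- prune_channels(s$recording, cfg$utility_channels)
    band_powers(segment_epochs(rec, cfg$epoch_length))
  })
  dplyr::bind_rows(parts)
}

# random positive band-power table, for algebraic identity checks
random_band_powers <- function(n = 200, seed = 5) {
  withr::with_seed(seed, {
    tibble::tibble(
      epoch = sprintf("e%03d", rep(seq_len(n / 2), 2)),
      subject = "subX",
      condition = "rest",
      level = 0L,
      channel = rep(c("CP1", "CP2"), each = n / 2),
      delta = stats::rlnorm(n), theta = stats::rlnorm(n),
      alpha = stats::rlnorm(n), beta = stats::rlnorm(n),
      gamma = stats::rlnorm(n)
    )
  })
}

# independent brute-force plug-in MI oracle (bits) over a count table;
# written as an explicit double loop, independent of the package internals
mi_brute_force <- function(counts) {
  total <- sum(counts)
  px <- rowSums(counts) / total
  py <- colSums(counts) / total
  s <- 0
  for (i in seq_len(nrow(counts))) {
    for (j in seq_len(ncol(counts))) {
      p <- counts[i, j] / total
      if (p > 0) s <- s + p * log2(p / (px[i] * py[j]))
    }
  }
  unname(s)
}

# epochs-by-channels toy matrix with named channels
toy_matrix <- function(n, channels, seed = 1) {
  withr::with_seed(seed, {
    m <- matrix(stats::rnorm(n * length(channels)), n, length(channels))
    colnames(m) <- channels
    m
  })
}
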