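# test-side oracle: equal-frequency binning + brute-force MI, written
# independently of the package's vectorised path
oracle_codes <- function(x, n_bins = 10) {
  br <- unique(quantile(x, probs = seq(0, 1, length.out = n_bins + 1),
                        names = FALSE))
  if (length(br) < 2) return(rep(1L, length(x)))
  cut(x, br, include.lowest = TRUE, labels = FALSE)
}
oracle_mi <- function(a, b) mi_brute_force(table(a, b))
oracle_D <- function(X, labels) {
  mean(vapply(seq_len(ncol(X)),
              function(j) oracle_mi(oracle_codes(X[, j]), labels), 0))
}
oracle_R <- function(X, include_diagonal = TRUE) {
  p <- ncol(X)
  s <- 0
  for (i in seq_len(p)) {
    for (j in seq_len(p)) {
      if (i == j && !include_diagonal) next
      s <- s + oracle_mi(oracle_codes(X[, i]), oracle_codes(X[, j]))
    }
  }
  s / p^2
}

test_that("relevance D averages per-channel MI (closed-form toys)", {
  # 3 channels, each an exact copy of a balanced binary label: D = 1 bit
  lab <- rep(0:1, each = 50)
  X <- matrix(rep(as.numeric(lab), 3), ncol = 3,
              dimnames = list(NULL, c("A", "B", "C")))
  expect_equal(as.numeric(relevance_D(X, lab)), 1)
  # 4 channels with per-channel MIs {1, 0, 0, 0}: D = 0.25
  X4 <- cbind(X[, 1, drop = FALSE], lab0 = 5, lab00 = 2, lab000 = 7)
  colnames(X4) <- c("A", "B", "C", "D")
  suppressWarnings(D4 <- relevance_D(X4, lab))
  expect_equal(as.numeric(D4), 0.25)
  expect_equal(unname(attr(D4, "per_channel")), c(1, 0, 0, 0))
})

test_that("redundancy of two identical channels is the binned entropy", {
  set.seed(12)
  x <- rnorm(400)
  X <- cbind(a = x, b = x)
  codes <- discretize(x)
  p <- tabulate(codes) / length(codes)
  h <- -sum(p[p > 0] * log2(p[p > 0]))
  expect_equal(redundancy_R(X), h, tolerance = 1e-12)
})

test_that("D, R and phi match brute-force double loops on small toys", {
  set.seed(13)
  for (rep_i in 1:3) {
    n <- 150
    labels <- sample(0:3, n, replace = TRUE)
    X <- matrix(rnorm(n * 5) + 0.4 * labels, n, 5,
                dimnames = list(NULL, paste0("ch", 1:5)))
    cfg_on <- evaluation_config()
    cfg_off <- evaluation_config(include_diagonal = FALSE)
    expect_equal(as.numeric(relevance_D(X, labels, cfg_on)),
                 oracle_D(X, labels), tolerance = 1e-12)
    expect_equal(redundancy_R(X, cfg_on), oracle_R(X, TRUE),
                 tolerance = 1e-12)
    expect_equal(redundancy_R(X, cfg_off), oracle_R(X, FALSE),
                 tolerance = 1e-12)
    pm <- phi_metric(X, labels, cfg_on)
    expect_identical(pm$phi, pm$D - pm$R)
    expect_equal(pm$phi, oracle_D(X, labels) - oracle_R(X, TRUE),
                 tolerance = 1e-12)
  }
})

test_that("phi cancels when labels and channels are all independent", {
  set.seed(14)
  n <- 2000
  labels <- sample(0:4, n, replace = TRUE)
  X <- matrix(rnorm(n * 6), n, 6, dimnames = list(NULL, paste0("ch", 1:6)))
  pm <- phi_metric(X, labels, evaluation_config(include_diagonal = FALSE))
  expect_lt(abs(pm$phi), 0.05)
})

test_that("phi is invariant to monotone per-channel rescaling", {
  set.seed(15)
  n <- 300
  labels <- sample(0:2, n, replace = TRUE)
  X <- matrix(rnorm(n * 4) + 0.5 * labels, n, 4,
              dimnames = list(NULL, paste0("ch", 1:4)))
  X2 <- X
  X2[, 1] <- exp(X[, 1])
  X2[, 2] <- X[, 2]^3
  X2[, 3] <- 10 * X[, 3] - 4
  pm1 <- phi_metric(X, labels)
  pm2 <- phi_metric(X2, labels)
  expect_equal(pm1$phi, pm2$phi, tolerance = 1e-12)
})

test_that("catalogue evaluation ranks all 26 indicators deterministically", {
  bp <- tiny_cohort_band_powers(n_subjects = 1, duration = 16, seed = 16)
  ind <- compute_indicators(bp)
  ev1 <- evaluate_indicators(ind)
  ev2 <- evaluate_indicators(ind)
  expect_equal(nrow(ev1), 26)
  expect_setequal(ev1$rank, 1:26)
  expect_identical(ev1$phi, ev2$phi)
  expect_identical(ev1$phi, ev1$D - ev1$R)
  # gamma modulation in the generator should surface a gamma indicator on top
  expect_true(ev1$uses_gamma[ev1$rank == 1])
  # normalised scores span [0, 1]
  expect_equal(max(ev1$score), 1)
  expect_equal(min(ev1$score), 0)
  expect_error(evaluate_indicators(dplyr::tibble(a = 1)),
               class = "eegworkload_error_config")
})

test_that("min-max normalisation maps extremes to 0 and 1 and keeps order", {
  v <- c(3, -1, 7, 2)
  f <- minmax_normalize(v)
  expect_equal(f[v == 7], 1)
  expect_equal(f[v == -1], 0)
  expect_equal(order(f), order(v))
  expect_error(minmax_normalize(rep(2, 5)),
               class = "eegworkload_error_degenerate")
})

test_that("the published reference evaluation normalises as printed", {
  ref <- reference_phi()
  expect_equal(nrow(ref), 26)
  f <- minmax_normalize(ref$phi_reference)
  expect_equal(f[ref$indicator_id == 16], 1)
  zero_ids <- c(7, 8, 9, 17, 25)
  expect_equal(f[ref$indicator_id %in% zero_ids], rep(0, 5))
  expect_equal(f[ref$indicator_id == 15],
               (3615.334366 - 0) / (3688.969054 - 0))
})
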