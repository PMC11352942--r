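#' Configuration for the synthetic EEG generator
#'
#' Defines the study conditions the generator emulates: a 64-channel montage
#' with 5 utility channels, five conditions in ascending workload order
#' (rest, then four control scenarios ordered by subjective workload
#' ratings: scenario1 < scenario2 < scenario4 < scenario3), a 1/f
#' background, and band-limited oscillatory activity whose amplitude on a
#' designated centro-parietal/temporo-parietal cluster grows with workload
#' level.
#'
#' Oscillatory power in a band sits on top of the background at
#' `osc_ratio` times the background's in-band power; on informative
#' channels the oscillatory amplitude in band `b` at workload level `l`
#' (0-based) is multiplied by `band_effect[[b]][l + 1]`.
#'
#' @param n_subjects Number of subjects in a cohort.
#' @param sampling_rate Sampling rate in Hz (integer-valued).
#' @param duration_per_condition Seconds of signal per condition.
#' @param conditions Condition names in ascending workload order; position
#'   defines the 0-based workload level.
#' @param channel_labels Full montage (default 64 labels).
#' @param utility_channels Labels treated as non-cortical utility lines.
#' @param informative_channels Labels whose band powers are modulated by
#'   workload level.
#' @param band_effect Named list, band -> per-level amplitude multipliers
#'   (length `length(conditions)`, positive, non-decreasing). Default: gamma
#'   amplitude doubles per level and beta rises 20% per level.
#' @param bands Band definitions, see [eeg_bands()].
#' @param noise_exponent Spectral slope alpha of the 1/f^alpha background.
#' @param background_sd Background amplitude (standard deviation, microvolts).
#' @param osc_ratio Oscillatory-to-background in-band power ratio at
#'   multiplier 1.
#' @param utility_sd White-noise amplitude of utility channels (microvolts).
#' @param subject_gain_sd Log-sd of per-subject, per-channel log-normal
#'   gains (inter-subject scale variability).
#' @param strong_channels Number of informative channels that carry the
#'   workload effect strongly for any one subject. Each subject gets a
#'   random subset of this size; a channel's band multipliers are raised to
#'   a per-subject weight drawn from `strong_weight_range` on that subset
#'   and from `weak_weight_range` elsewhere. This makes the best channel
#'   vary from person to person while the cluster as a whole stays
#'   informative -- the reason single-channel detection is unstable across
#'   subjects and small combinations are not.
#' @param strong_weight_range,weak_weight_range Uniform ranges for the
#'   effect weights of strong and weak informative channels. Set
#'   `strong_channels` to the cluster size and `strong_weight_range` to
#'   `c(1, 1)` for homogeneous effects.
#' @param epoch_length Nominal epoch length in seconds (used to require at
#'   least two epochs per condition).
#' @param seed Master seed; per-subject seeds are derived from it.
#' @return A validated list of class `sim_config`.
#' @export
#' @examples
#' cfg <- sim_config(n_subjects = 2, duration_per_condition = 12,
#'                   sampling_rate = 128)
#' cfg$conditions
sim_config <- function(n_subjects = 41,
                       sampling_rate = 250,
                       duration_per_condition = 120,
                       conditions = c("rest", "scenario1", "scenario2",
                                      "scenario4", "scenario3"),
                       channel_labels = default_montage(),
                       utility_channels = eegworkload::utility_channels(),
                       informative_channels = eegworkload::informative_channels(),
                       band_effect = list(beta = 1.2^(0:4), gamma = 2^(0:4)),
                       bands = eeg_bands(),
                       noise_exponent = 1,
                       background_sd = 3,
                       osc_ratio = 4,
                       utility_sd = 10,
                       subject_gain_sd = 0.1,
                       strong_channels = 3,
                       strong_weight_range = c(0.7, 1),
                       weak_weight_range = c(0.05, 0.3),
                       epoch_length = 2,
                       seed = 1L) {
  check_positive_scalar(n_subjects, "n_subjects")
  check_positive_scalar(sampling_rate, "sampling_rate")
  check_positive_scalar(duration_per_condition, "duration_per_condition")
  check_positive_scalar(epoch_length, "epoch_length")
  if (sampling_rate != round(sampling_rate)) {
    abort_eeg("`sampling_rate` must be an integer number of Hz.",
              class = "eegworkload_error_config")
  }
  if (!all(utility_channels %in% channel_labels)) {
    abort_eeg("All utility_channels must be montage labels.",
              class = "eegworkload_error_config")
  }
  if (!all(informative_channels %in% channel_labels)) {
    abort_eeg("All informative_channels must be montage labels.",
              class = "eegworkload_error_config")
  }
  if (length(intersect(informative_channels, utility_channels)) > 0) {
    abort_eeg("informative_channels and utility_channels must be disjoint.",
              class = "eegworkload_error_config")
  }
  if (duration_per_condition < 2 * epoch_length) {
    abort_eeg("Each condition must be long enough for at least 2 epochs.",
              class = "eegworkload_error_config")
  }
  for (nm in c("strong_weight_range", "weak_weight_range")) {
    rg <- get(nm)
    if (length(rg) != 2 || any(rg < 0) || any(rg > 1) || diff(rg) < 0) {
      abort_eeg(sprintf("`%s` must be c(low, high) within [0, 1].", nm),
                class = "eegworkload_error_config")
    }
  }
  if (!is_scalar_number(strong_channels) || strong_channels < 1 ||
      strong_channels > length(informative_channels)) {
    abort_eeg("`strong_channels` must be between 1 and the informative cluster size.",
              class = "eegworkload_error_config")
  }
  n_lev <- length(conditions)
  if (!all(names(band_effect) %in% bands$band)) {
    abort_eeg("band_effect names must be band names.",
              class = "eegworkload_error_config")
  }
  for (b in names(band_effect)) {
    m <- band_effect[[b]]
    if (length(m) != n_lev || any(m <= 0) || any(diff(m) < 0)) {
      abort_eeg(sprintf(
        "band_effect$%s must be %d positive non-decreasing multipliers.",
        b, n_lev), class = "eegworkload_error_config")
    }
  }
  structure(
    list(n_subjects = as.integer(n_subjects),
         sampling_rate = as.integer(sampling_rate),
         duration_per_condition = duration_per_condition,
         conditions = conditions,
         channel_labels = channel_labels,
         utility_channels = utility_channels,
         informative_channels = informative_channels,
         band_effect = band_effect,
         bands = bands,
         noise_exponent = noise_exponent,
         background_sd = background_sd,
         osc_ratio = osc_ratio,
         utility_sd = utility_sd,
         subject_gain_sd = subject_gain_sd,
         strong_channels = as.integer(strong_channels),
         strong_weight_range = strong_weight_range,
         weak_weight_range = weak_weight_range,
         epoch_length = epoch_length,
         seed = as.integer(seed)),
    class = "sim_config")
}

# two-sided FFT-bin frequencies for n samples at fs Hz
fft_freqs <- function(n, fs) {
  k <- 0:(n - 1)
  pmin(k, n - k) * fs / n
}

# amplitude shape of the 1/f^alpha background, unit-variance normalised later
background_shape <- function(f, alpha) {
  s <- numeric(length(f))
  fl <- pmax(f, 0.5)  # flatten below 0.5 Hz to keep the DC region finite
  s <- fl^(-alpha / 2)
  s[f == 0] <- 0
  s
}

# band multiplier profile: sqrt(1 + osc_ratio * mult_b^2) inside band b
band_shape_factor <- function(f, bands, mults, osc_ratio) {
  fac <- rep(1, length(f))
  for (i in seq_len(nrow(bands))) {
    b <- bands$band[i]
    m <- mults[[b]] %||% 1
    sel <- f >= bands$low[i] & f < bands$high[i]
    fac[sel] <- sqrt(1 + osc_ratio * m^2)
  }
  fac
}

# synthesise n samples x n_ch channels of coloured noise with amplitude
# spectrum shape (length n, symmetric in FFT bins)
spectral_noise <- function(n, n_ch, shape) {
  x <- matrix(rnorm(n * n_ch), n, n_ch)
  X <- mvfft(x)
  Y <- X * shape
  Re(mvfft(Y, inverse = TRUE)) / n
}

#' Simulate one subject's continuous recording
#'
#' Generates a continuous multichannel recording laid out as consecutive
#' condition blocks (in the configured ascending-workload order), together
#' with a ground-truth manifest. Identical `(config, subject)` input yields
#' identical output.
#'
#' @param config A [sim_config()].
#' @param subject Positive integer subject index (1-based); the subject
#'   label is `subNN` and the per-subject seed is derived from
#'   `config$seed` and this index.
#' @return A list with elements `recording` ([eeg_recording]) and
#'   `manifest` (ground truth: condition levels, informative channels, band
#'   effects, per-channel gains, seed).
#' @export
#' @examples
#' cfg <- sim_config(n_subjects = 1, duration_per_condition = 8,
#'                   sampling_rate = 128, seed = 7)
#' sim <- simulate_subject(cfg, 1)
#' sim$recording
simulate_subject <- function(config, subject = 1L) {
  if (!inherits(config, "sim_config")) {
    abort_eeg("`config` must be created by sim_config().",
              class = "eegworkload_error_config")
  }
  if (!is_scalar_number(subject) || subject < 1 || subject != round(subject)) {
    abort_eeg("`subject` must be a positive integer index.",
              class = "eegworkload_error_config")
  }
  subject <- as.integer(subject)
  subject_id <- sprintf("sub%02d", subject)
  fs <- config$sampling_rate
  n_cond <- length(config$conditions)
  n_per <- round(config$duration_per_condition * fs)
  labels <- config$channel_labels
  n_ch <- length(labels)
  is_util <- labels %in% config$utility_channels
  is_info <- labels %in% config$informative_channels

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  set.seed(derive_seed(config$seed, subject))

  gains <- exp(rnorm(n_ch, sd = config$subject_gain_sd))
  names(gains) <- labels
  # per-subject effect weights: each subject expresses the workload effect
  # strongly on a random subset of the informative cluster and weakly on
  # the rest, so the best channel differs from person to person
  info_labels <- labels[is_info]
  strong <- sample(info_labels, config$strong_channels)
  weights <- ifelse(
    info_labels %in% strong,
    runif(length(info_labels), config$strong_weight_range[1],
          config$strong_weight_range[2]),
    runif(length(info_labels), config$weak_weight_range[1],
          config$weak_weight_range[2]))
  names(weights) <- info_labels

  f <- fft_freqs(n_per, fs)
  bg <- background_shape(f, config$noise_exponent)
  # scale so the background component alone has sd background_sd
  bg <- bg * config$background_sd / sqrt(mean(bg^2))
  base_fac <- band_shape_factor(f, config$bands,
                                mults = list(), osc_ratio = config$osc_ratio)

  blocks <- vector("list", n_cond)
  for (k in seq_len(n_cond)) {
    block <- matrix(0, n_ch, n_per)
    n_plain <- sum(!is_util & !is_info)
    if (n_plain > 0) {
      block[!is_util & !is_info, ] <-
        t(spectral_noise(n_per, n_plain, bg * base_fac))
    }
    for (lab_i in info_labels) {
      mults_w <- lapply(config$band_effect,
                        function(m) m[k]^weights[[lab_i]])
      fac <- band_shape_factor(f, config$bands, mults_w, config$osc_ratio)
      block[match(lab_i, labels), ] <- spectral_noise(n_per, 1, bg * fac)
    }
    if (any(is_util)) {
      block[is_util, ] <- matrix(rnorm(sum(is_util) * n_per,
                                       sd = config$utility_sd),
                                 sum(is_util), n_per)
    }
    blocks[[k]] <- block
  }
  samples <- do.call(cbind, blocks) * gains

  intervals <- tibble(
    condition = config$conditions,
    start = (seq_len(n_cond) - 1) * config$duration_per_condition,
    end = seq_len(n_cond) * config$duration_per_condition
  )
  levels <- setNames(seq_len(n_cond) - 1L, config$conditions)
  rec <- eeg_recording(samples, fs, labels, intervals,
                       subject_id = subject_id, condition_levels = levels)
  manifest <- structure(
    list(subject_id = subject_id,
         condition_levels = as.list(levels),
         informative_channels = config$informative_channels,
         utility_channels = config$utility_channels,
         band_effect = config$band_effect,
         strong_channels = as.character(strong),
         effect_weights = as.list(weights),
         noise_exponent = config$noise_exponent,
         subject_gains = as.list(gains),
         seed = config$seed,
         subject_seed = derive_seed(config$seed, subject)),
    class = "eeg_manifest")
  list(recording = rec, manifest = manifest)
}

#' Simulate a cohort of subjects
#'
#' @param config A [sim_config()]; `config$n_subjects` recordings are
#'   generated with deterministically derived per-subject seeds, so subjects
#'   differ in realised noise but share the effect structure.
#' @return A list of `list(recording, manifest)` pairs, one per subject.
#' @export
simulate_cohort <- function(config) {
  if (!inherits(config, "sim_config")) {
    abort_eeg("`config` must be created by sim_config().",
              class = "eegworkload_error_config")
  }
  lapply(seq_len(config$n_subjects), function(i) simulate_subject(config, i))
}

#' Write / read a ground-truth manifest as JSON
#'
#' @param manifest A manifest from [simulate_subject()].
#' @param path File path.
#' @return `read_manifest()` returns the manifest; `write_manifest()` its
#'   path, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(unclass(manifest), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  m$condition_levels <- as.list(m$condition_levels)
  m$subject_gains <- as.list(m$subject_gains)
  m$effect_weights <- as.list(m$effect_weights)
  m$band_effect <- lapply(m$band_effect, as.numeric)
  structure(m, class = "eeg_manifest")
}
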