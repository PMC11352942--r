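#' Discretization scheme for the plug-in MI estimator
#'
#' @param method `"equal_frequency"` (quantile bins, default -- robust to
#'   the heavy-tailed distributions of band powers) or `"equal_width"`.
#' @param n_bins Number of bins (>= 2), default 10.
#' @return A list of class `discretization_scheme`.
#' @export
discretization_scheme <- function(method = c("equal_frequency", "equal_width"),
                                  n_bins = 10) {
  method <- match.arg(method)
  if (!is_scalar_number(n_bins) || n_bins < 2 || n_bins != round(n_bins)) {
    abort_eeg("`n_bins` must be an integer >= 2.",
              class = "eegworkload_error_config")
  }
  structure(list(method = method, n_bins = as.integer(n_bins)),
            class = "discretization_scheme")
}

#' Discretize a continuous series
#'
#' Maps every observation to exactly one bin. A constant series collapses to
#' a single bin with a warning (its entropy, and any MI with it, is then 0).
#'
#' @param x Numeric vector.
#' @param scheme A [discretization_scheme()].
#' @return Integer codes in `1..n_bins_effective`, with attribute `n_bins`.
#' @export
discretize <- function(x, scheme = discretization_scheme()) {
  if (!is.numeric(x) || length(x) == 0) {
    abort_eeg("`x` must be a non-empty numeric vector.",
              class = "eegworkload_error_config")
  }
  if (anyNA(x)) {
    abort_eeg("`x` must not contain missing values.",
              class = "eegworkload_error_config")
  }
  breaks <- if (scheme$method == "equal_frequency") {
    unique(quantile(x, probs = seq(0, 1, length.out = scheme$n_bins + 1),
                    names = FALSE, type = 7))
  } else {
    seq(min(x), max(x), length.out = scheme$n_bins + 1)
  }
  if (length(unique(breaks)) < 2) {
    warning("Constant series: falling back to a single bin (MI will be 0).",
            call. = FALSE)
    codes <- rep(1L, length(x))
    attr(codes, "n_bins") <- 1L
    return(codes)
  }
  codes <- cut(x, breaks = breaks, include.lowest = TRUE, labels = FALSE)
  codes <- as.integer(codes)
  attr(codes, "n_bins") <- length(breaks) - 1L
  codes
}

# core plug-in MI in bits from a (cleaned) count matrix
mi_from_counts <- function(counts) {
  total <- sum(counts)
  p <- counts / total
  px <- rowSums(p)
  py <- colSums(p)
  pos <- p > 0
  sum(p[pos] * log2(p[pos] / (px[row(p)][pos] * py[col(p)][pos])))
}

#' Plug-in mutual information of a 2-way contingency table
#'
#' Shannon mutual information (bits) of the empirical joint distribution,
#' with the `0 * log 0 = 0` convention.
#'
#' @param joint_counts Non-negative matrix or 2-way table of counts with a
#'   positive total.
#' @return MI in bits (a single non-negative number).
#' @export
#' @examples
#' mi_discrete(matrix(c(50, 0, 0, 50), 2))   # 1 bit
#' mi_discrete(matrix(25, 2, 2))             # 0 bits
mi_discrete <- function(joint_counts) {
  counts <- as.matrix(joint_counts)
  if (length(counts) == 0 || any(is.na(counts)) || any(counts < 0)) {
    abort_eeg("`joint_counts` must be a non-negative count matrix.",
              class = "eegworkload_error_config")
  }
  if (sum(counts) <= 0) {
    abort_eeg("`joint_counts` must have a positive total.",
              class = "eegworkload_error_config")
  }
  mi_from_counts(counts)
}

# contingency table of two integer code vectors via a joint linear index
joint_counts <- function(cx, nx, cy, ny) {
  idx <- (as.integer(cy) - 1L) * nx + as.integer(cx)
  matrix(tabulate(idx, nbins = nx * ny), nrow = nx, ncol = ny)
}

codes_of <- function(v) {
  f <- factor(v)
  list(codes = as.integer(f), n = nlevels(f))
}

#' MI between a continuous series and a categorical label
#'
#' Discretizes `x` by `scheme`, then applies the plug-in estimator against
#' the labels. This is the estimator behind the relevance term of the
#' indicator-evaluation statistic.
#'
#' @param x Numeric vector.
#' @param c Categorical series (factor or vector) of the same length with at
#'   least 2 distinct values.
#' @param scheme A [discretization_scheme()].
#' @return MI in bits.
#' @export
mi_continuous_discrete <- function(x, c, scheme = discretization_scheme()) {
  if (length(x) != length(c)) {
    abort_eeg("`x` and `c` must have equal length.",
              class = "eegworkload_error_config")
  }
  lab <- codes_of(c)
  if (lab$n < 2) {
    abort_eeg("`c` must have at least 2 distinct labels.",
              class = "eegworkload_error_config")
  }
  cx <- discretize(x, scheme)
  mi_from_counts(joint_counts(cx, attr(cx, "n_bins"), lab$codes, lab$n))
}

#' MI between two continuous series
#'
#' Discretizes each axis by `scheme`, then applies the plug-in estimator to
#' the 2-D histogram. This is the estimator behind the redundancy term.
#'
#' @param x,y Numeric vectors of equal length.
#' @param scheme A [discretization_scheme()].
#' @return MI in bits.
#' @export
mi_continuous_continuous <- function(x, y, scheme = discretization_scheme()) {
  if (length(x) != length(y)) {
    abort_eeg("`x` and `y` must have equal length.",
              class = "eegworkload_error_config")
  }
  cx <- discretize(x, scheme)
  cy <- discretize(y, scheme)
  mi_from_counts(joint_counts(cx, attr(cx, "n_bins"), cy, attr(cy, "n_bins")))
}

# --- fast internals used by the evaluation and channel-selection modules ---

# discretize every column of a matrix; returns integer matrix + bin counts
code_matrix <- function(X, scheme) {
  codes <- matrix(0L, nrow(X), ncol(X), dimnames = dimnames(X))
  n_bins <- integer(ncol(X))
  for (j in seq_len(ncol(X))) {
    cj <- discretize(X[, j], scheme)
    codes[, j] <- cj
    n_bins[j] <- attr(cj, "n_bins")
  }
  list(codes = codes, n_bins = n_bins)
}

# full pairwise plug-in MI matrix (bits) among columns of a code matrix,
# via one-hot cross-products: MI(i,j) = H_i + H_j - H_ij. The diagonal is
# the marginal entropy H_i = I(x_i, x_i).
pairwise_mi <- function(codes, n_bins) {
  n <- nrow(codes); p <- ncol(codes)
  B <- max(n_bins)
  onehot <- lapply(seq_len(B), function(a) (codes == a) * 1)
  marg <- vapply(onehot, colSums, numeric(p))        # p x B counts
  pm <- marg / n
  H <- -rowSums(ifelse(pm > 0, pm * log2(pm), 0))
  Hij <- matrix(0, p, p)
  for (a in seq_len(B)) {
    Ma <- onehot[[a]]
    for (b in seq_len(B)) {
      N <- crossprod(Ma, onehot[[b]]) / n            # joint p_ab per pair
      pos <- N > 0
      Hij[pos] <- Hij[pos] - N[pos] * log2(N[pos])
    }
  }
  M <- outer(H, H, "+") - Hij
  dimnames(M) <- list(colnames(codes), colnames(codes))
  # clamp tiny negative rounding residue
  M[M < 0 & M > -1e-12] <- 0
  M
}

# MI of each code column against a label vector
relevance_mi <- function(codes, n_bins, labels) {
  lab <- codes_of(labels)
  vapply(seq_len(ncol(codes)), function(j) {
    mi_from_counts(joint_counts(codes[, j], n_bins[j], lab$codes, lab$n))
  }, 0)
}
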