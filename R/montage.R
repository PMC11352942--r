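#' Default 64-channel montage
#'
#' Extended 10-20 labels for a 64-channel wireless acquisition cap: 59
#' cortical electrodes plus 5 non-cortical utility channels (ocular, cardiac,
#' muscular and trigger lines) that carry no scalp signal and are pruned
#' before analysis.
#'
#' @param include_utility If `FALSE`, return only the 59 cortical labels.
#' @return Character vector of channel labels (64, or 59 without utility).
#' @seealso [utility_channels()], [informative_channels()]
#' @export
#' @examples
#' length(default_montage())            # 64
#' length(default_montage(FALSE))       # 59
default_montage <- function(include_utility = TRUE) {
  cortical <- c(
    "Fp1", "Fp2", "AF3", "AF4",
    "F7", "F5", "F3", "F1", "Fz", "F2", "F4", "F6", "F8",
    "FT7", "FC5", "FC3", "FC1", "FCz", "FC2", "FC4", "FC6", "FT8",
    "T7", "C5", "C3", "C1", "Cz", "C2", "C4", "C6", "T8",
    "TP7", "CP5", "CP3", "CP1", "CPz", "CP2", "CP4", "CP6", "TP8",
    "P7", "P5", "P3", "P1", "Pz", "P2", "P4", "P6", "P8",
    "PO7", "PO5", "PO3", "POz", "PO4", "PO6", "PO8",
    "O1", "Oz", "O2"
  )
  if (include_utility) c(cortical, utility_channels()) else cortical
}

#' Default utility (non-cortical) channel labels
#'
#' @return Character vector of 5 labels: ocular (VEO, HEO), cardiac (EKG),
#'   muscular (EMG) and the trigger line (TRIG).
#' @export
utility_channels <- function() {
  c("VEO", "HEO", "EKG", "EMG", "TRIG")
}

#' Default workload-informative channel cluster
#'
#' The centro-parietal / temporo-parietal cluster that the synthetic
#' generator modulates with workload by default.
#'
#' @return Character vector of 6 labels.
#' @export
informative_channels <- function() {
  c("CP2", "CP3", "CP4", "CP5", "CP6", "TP7")
}
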