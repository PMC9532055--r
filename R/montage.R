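#' The 21-electrode standard 10-20 montage
#'
#' Ordered electrode names of the 21 standard scalp positions of the
#' international 10-20 system, the fixed channel order used throughout the
#' pipeline.
#'
#' @return Character vector of 21 electrode names.
#' @examples
#' standardMontage21()
#' @export
standardMontage21 <- function() {
  c("FP1", "FP2", "F7", "F3", "FZ", "F4", "F8", "A1", "T3", "C3", "CZ",
    "C4", "T4", "A2", "T5", "P3", "PZ", "P4", "T6", "O1", "O2")
}

#' Normalize EEG channel labels
#'
#' Clinical EDF channel labels typically decorate the electrode name with a
#' modality prefix and a reference suffix (e.g. `"EEG FP1-REF"`,
#' `"EEG T3-LE"`).  This strips both and upper-cases the result so labels
#' can be matched against [standardMontage21()].
#'
#' @param labels Character vector of raw channel labels.
#' @return Character vector of bare upper-case electrode names.
#' @examples
#' normalizeChannelLabels(c("EEG FP1-REF", "eeg o2-LE", "CZ"))
#' @export
normalizeChannelLabels <- function(labels) {
  x <- toupper(trimws(labels))
  x <- sub("^EEG\\s+", "", x)
  x <- sub("-[A-Z0-9]+$", "", x)
  trimws(x)
}

#' Brain-region electrode map
#'
#' The six scalp regions used by the region-reduction ablation, partitioning
#' the 21-electrode montage: frontal, temporal, ear, parietal, occipital and
#' motor cortex.
#'
#' @return Named list mapping region name to electrode names; the regions
#'   are disjoint and their union is [standardMontage21()].
#' @examples
#' regionMap()$occipital
#' @export
regionMap <- function() {
  list(
    frontal      = c("FP1", "FP2", "F7", "F8", "F3", "F4", "FZ"),
    temporal     = c("T3", "T5", "T4", "T6"),
    ear          = c("A1", "A2"),
    parietal     = c("P3", "P4", "PZ"),
    occipital    = c("O1", "O2"),
    motor_cortex = c("C3", "C4", "CZ")
  )
}
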