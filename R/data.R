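#' Published TUH EEG Abnormal Corpus v2.0.0 bookkeeping counts
#'
#' File and patient counts per subset and class of the corpus release the
#' detection protocol was developed on.  The corpus itself is
#' registration-gated and is not shipped; these counts support
#' bookkeeping checks (e.g. the test subset comprises 150 normal + 126
#' pathological = 276 recordings).
#'
#' @return Data frame with columns `subset`, `class`, `files`, `patients`.
#' @examples
#' cc <- corpusCounts()
#' sum(cc$files[cc$subset == "testing"])
#' @export
corpusCounts <- function() {
  read.csv(system.file("extdata", "tuh_abnormal_v2_counts.csv",
                       package = "eegpath"))
}

#' Published reference confusion matrices
#'
#' The confusion counts reported for the strongest published configuration
#' of this detection protocol (680-tree depth-4 booster) on the TUH
#' abnormal corpus: the 10-fold cross-validation matrix and the held-out
#' default test set matrix.  Used as fixed inputs for verifying the
#' metric arithmetic, not as results of this package.
#'
#' @return Data frame with columns `evaluation` (`"cv"`, `"test"`),
#'   `TN`, `FP`, `FN`, `TP`.
#' @examples
#' metricsFromConfusion(
#'   c(TP = 107, TN = 139, FP = 11, FN = 19), percent = TRUE)
#' @export
referenceConfusions <- function() {
  read.csv(system.file("extdata", "reference_confusion_matrices.csv",
                       package = "eegpath"))
}
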