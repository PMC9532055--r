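#' Multi-scale aggregation configuration
#'
#' @param scales Subset of `c("front", "rear", "global")`, the temporal
#'   scales over which the segment axis is collapsed by standard
#'   deviation; default all three.
#' @param includeAge Append the patient age (years, unscaled) as the final
#'   entry (default `TRUE`).
#' @return A validated `AggregationConfig` list.
#' @export
aggregationConfig <- function(scales = c("front", "rear", "global"),
                              includeAge = TRUE) {
  scales <- match.arg(scales, several.ok = TRUE)
  if (!length(scales))
    stopf("at least one aggregation scale required",
          class = "invalidConfigError")
  ## fixed canonical order regardless of how the user listed them
  scales <- intersect(c("front", "rear", "global"), scales)
  structure(list(scales = scales, includeAge = isTRUE(includeAge)),
            class = "AggregationConfig")
}

## population SD over the segment axis of a C x S x F array, for a given
## segment index subset; returns a C x F matrix
#' @noRd
segmentSd <- function(values, idx) {
  d <- dim(values)
  sub <- values[, idx, , drop = FALSE]
  m <- matrix(aperm(sub, c(2, 1, 3)), nrow = length(idx))  # S' x (C*F)
  matrix(colPopSd(m), d[1], d[3])
}

#' Multi-scale aggregation of a feature tensor
#'
#' Collapses the time (segment) axis of a channels x segments x features
#' tensor: for every (channel, feature) pair the standard deviation is
#' taken over the front half of the segments (1..ceiling(S/2)), the rear
#' half, and all segments (global).  The result is flattened
#' channel-major (channel, then scale in order front/rear/global, then
#' feature) and the patient age is appended when configured — the
#' per-recording classifier input of length `C * |scales| * F (+ 1)`.
#'
#' @param tensor A [FeatureTensor-class] with time-ordered segments.
#' @param config An [aggregationConfig()].
#' @return Named numeric vector.
#' @examples
#' # 21 channels x 100 segments x 24 features -> 21*3*24 + 1 = 1513 values
#' @export
aggregateFeatures <- function(tensor, config = aggregationConfig()) {
  stopifnot(is(tensor, "FeatureTensor"), inherits(config, "AggregationConfig"))
  d <- dim(tensor@values)
  C <- d[1]; S <- d[2]; FF <- d[3]
  local <- any(c("front", "rear") %in% config$scales)
  if (local && S < 2L)
    stopf("local aggregation needs at least 2 segments (got %d)", S,
          class = "insufficientSegmentsError")
  half <- ceiling(S / 2)
  idxOf <- list(front = seq_len(half),
                rear = seq.int(half + 1L, S),
                global = seq_len(S))
  parts <- lapply(config$scales, function(sc) segmentSd(tensor@values,
                                                        idxOf[[sc]]))
  ## channel-major flatten: feature fastest, then scale, then channel
  nScale <- length(parts)
  v <- numeric(C * nScale * FF)
  nm <- character(C * nScale * FF)
  pos <- 0L
  for (ch in seq_len(C)) {
    for (k in seq_len(nScale)) {
      v[pos + seq_len(FF)] <- parts[[k]][ch, ]
      nm[pos + seq_len(FF)] <- paste(tensor@channelLabels[ch],
                                     config$scales[k],
                                     tensor@featureNames, sep = "_")
      pos <- pos + FF
    }
  }
  names(v) <- nm
  if (config$includeAge) {
    v <- c(v, age = tensor@age)
  }
  v
}

#' Feature-construction variants for the aggregation ablation
#'
#' Four ways of turning a feature tensor into a classifier row:
#' \describe{
#'   \item{case 1}{no aggregation — the raw C x S x F tensor flattened
#'     (channel-major, then segment, then feature) with age appended.}
#'   \item{case 2}{global scale only, plus age (`C*F + 1`).}
#'   \item{case 3}{local scales only (front + rear), plus age
#'     (`C*2*F + 1`).}
#'   \item{case 4}{full multi-scale aggregation with age (`C*3*F + 1`);
#'     identical to [aggregateFeatures()] under defaults.}
#' }
#'
#' @param tensor A [FeatureTensor-class].
#' @param case Integer 1-4.
#' @param includeAge Append age (default `TRUE`).
#' @return Named numeric vector.
#' @export
buildFeatureVariant <- function(tensor, case, includeAge = TRUE) {
  stopifnot(is(tensor, "FeatureTensor"))
  if (!case %in% 1:4)
    stopf("case must be 1, 2, 3 or 4", class = "invalidConfigError")
  if (case == 1L) {
    d <- dim(tensor@values)
    ## channel-major, then segment, then feature
    v <- as.vector(aperm(tensor@values, c(3, 2, 1)))
    nm <- as.vector(outer(
      tensor@featureNames,
      as.vector(outer(sprintf("s%03d", seq_len(d[2])), tensor@channelLabels,
                      function(s, ch) paste(ch, s, sep = "_"))),
      function(f, cs) paste(cs, f, sep = "_")))
    names(v) <- nm
    if (includeAge) v <- c(v, age = tensor@age)
    return(v)
  }
  scales <- switch(case - 1L,
                   "global",                    # case 2
                   c("front", "rear"),          # case 3
                   c("front", "rear", "global")) # case 4
  aggregateFeatures(tensor, aggregationConfig(scales, includeAge))
}

#' Cohort design matrix as a SummarizedExperiment
#'
#' Builds the classifier input for a cohort of feature tensors: one
#' aggregated row per recording, stored features x recordings in the assay
#' with `age` and `label` in `colData`.
#'
#' @param tensors List of [FeatureTensor-class] objects (equal layouts).
#' @param case Aggregation variant 1-4 (see [buildFeatureVariant()]).
#' @param includeAge Append age as a feature (default `TRUE`).
#' @return A [SummarizedExperiment][SummarizedExperiment::SummarizedExperiment-class]
#'   with assay `features`.
#' @export
designMatrix <- function(tensors, case = 4L, includeAge = TRUE) {
  if (!length(tensors))
    stopf("empty tensor list", class = "invalidInputError")
  rows <- lapply(tensors, buildFeatureVariant, case = case,
                 includeAge = includeAge)
  p <- lengths(rows)
  if (length(unique(p)) != 1L)
    stopf("tensors produce ragged rows (%s features)",
          paste(unique(p), collapse = "/"), class = "layoutError")
  mat <- do.call(cbind, rows)
  colnames(mat) <- vapply(tensors, recordingId, character(1))
  SummarizedExperiment(
    assays = list(features = mat),
    colData = DataFrame(
      recordingId = vapply(tensors, recordingId, character(1)),
      age = vapply(tensors, patientAge, numeric(1)),
      label = vapply(tensors, classLabel, integer(1))
    )
  )
}

#' Classifier rows and labels from a design matrix
#'
#' @param se A [designMatrix()] result.
#' @return List with `x` (recordings x features matrix) and `label`
#'   (integer vector).
#' @export
designRows <- function(se) {
  list(x = t(assay(se, "features")), label = colData(se)$label)
}

#' Write a design matrix to CSV
#'
#' One row per recording; feature columns named
#' `<channel>_<scale>_<statistic>_<subband>`, plus `age`, plus
#' `recording_id` and `label` metadata columns.
#'
#' @param se A [designMatrix()] result.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
writeDesignMatrix <- function(se, path) {
  df <- data.frame(recording_id = colData(se)$recordingId,
                   label = colData(se)$label,
                   t(assay(se, "features")), check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a design matrix CSV back into matrix form
#'
#' @param path CSV written by [writeDesignMatrix()].
#' @return List with `x` (recordings x features), `label`, `recordingId`.
#' @export
readDesignMatrix <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  x <- as.matrix(df[, setdiff(colnames(df), c("recording_id", "label")),
                    drop = FALSE])
  rownames(x) <- df$recording_id
  list(x = x, label = as.integer(df$label),
       recordingId = as.character(df$recording_id))
}
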