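#' @name eegpath-generics
#' @title Accessor generics for eegpath containers
#' @description Small accessor generics shared by the S4 containers:
#'   channel labels, sampling rate, patient age, class label and
#'   recording identifier.
#' @param x An eegpath S4 object.
#' @return The corresponding slot value.
NULL

#' @rdname eegpath-generics
#' @export
setGeneric("channelLabels", function(x) standardGeneric("channelLabels"))

#' @rdname eegpath-generics
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))

#' @rdname eegpath-generics
#' @export
setGeneric("patientAge", function(x) standardGeneric("patientAge"))

#' @rdname eegpath-generics
#' @export
setGeneric("classLabel", function(x) standardGeneric("classLabel"))

#' @rdname eegpath-generics
#' @export
setGeneric("recordingId", function(x) standardGeneric("recordingId"))

#' @rdname eegpath-generics
#' @export
setGeneric("signalMatrix", function(x) standardGeneric("signalMatrix"))

#' @rdname eegpath-generics
#' @export
setGeneric("featureValues", function(x) standardGeneric("featureValues"))

#' @rdname eegpath-generics
#' @export
setGeneric("featureNames", function(x) standardGeneric("featureNames"))

#' @rdname eegpath-generics
#' @export
setGeneric("segmentArray", function(x) standardGeneric("segmentArray"))


#' EEGRecording: one subject's multichannel EEG
#'
#' Holds a channels-by-samples signal matrix in microvolts together with
#' channel labels, sampling rate and per-patient metadata (age in years,
#' optional binary class label where 1 = pathological, 0 = normal).
#'
#' @slot signal Numeric matrix, channels x samples (µV).
#' @slot channelLabels Character vector, one label per signal row.
#' @slot samplingRate Sampling rate in Hz.
#' @slot age Patient age in years (non-negative; infants allowed).
#' @slot label Integer class label, 0 = normal, 1 = pathological, or NA.
#' @slot recordingId Opaque identifier string.
#'
#' @exportClass EEGRecording
setClass("EEGRecording",
  representation(
    signal = "matrix",
    channelLabels = "character",
    samplingRate = "numeric",
    age = "numeric",
    label = "integer",
    recordingId = "character"
  ),
  prototype(
    signal = matrix(numeric(0), 0, 0),
    channelLabels = character(0),
    samplingRate = 250,
    age = NA_real_,
    label = NA_integer_,
    recordingId = ""
  )
)

setValidity("EEGRecording", function(object) {
  msg <- character(0)
  if (nrow(object@signal) != length(object@channelLabels))
    msg <- c(msg, "number of signal rows must equal number of channel labels")
  if (length(object@samplingRate) != 1L || !is.finite(object@samplingRate) ||
      object@samplingRate <= 0)
    msg <- c(msg, "samplingRate must be a positive scalar")
  if (length(object@age) != 1L || (!is.na(object@age) && object@age < 0))
    msg <- c(msg, "age must be a non-negative scalar or NA")
  if (length(object@label) != 1L ||
      (!is.na(object@label) && !object@label %in% c(0L, 1L)))
    msg <- c(msg, "label must be 0, 1 or NA")
  if (anyDuplicated(object@channelLabels))
    msg <- c(msg, "channel labels must be unique")
  if (length(msg)) msg else TRUE
})

#' Construct an EEGRecording
#'
#' @param signal Numeric matrix, channels x samples (µV).
#' @param channelLabels Character vector of channel names.
#' @param samplingRate Sampling rate in Hz.
#' @param age Patient age in years (NA if unknown).
#' @param label Class label: 0 normal, 1 pathological, NA unknown.
#' @param recordingId Identifier string.
#' @return An [EEGRecording-class] object.
#' @examples
#' rec <- EEGRecording(matrix(rnorm(500), 2, 250), c("C3", "C4"), 250)
#' rec
#' @export
EEGRecording <- function(signal, channelLabels, samplingRate = 250,
                         age = NA_real_, label = NA_integer_,
                         recordingId = "rec") {
  if (!is.matrix(signal)) signal <- matrix(signal, nrow = 1L)
  new("EEGRecording", signal = signal,
      channelLabels = as.character(channelLabels),
      samplingRate = as.numeric(samplingRate),
      age = as.numeric(age),
      label = as.integer(label),
      recordingId = as.character(recordingId))
}

#' SegmentedEEG: a recording cut into equal non-overlapping windows
#'
#' @slot segments Numeric array, channels x segments x samplesPerSegment.
#' @slot channelLabels Character vector of channel names.
#' @slot samplingRate Sampling rate in Hz.
#' @slot age Patient age in years.
#' @slot label Integer class label or NA.
#' @slot recordingId Identifier string.
#'
#' @exportClass SegmentedEEG
setClass("SegmentedEEG",
  representation(
    segments = "array",
    channelLabels = "character",
    samplingRate = "numeric",
    age = "numeric",
    label = "integer",
    recordingId = "character"
  )
)

setValidity("SegmentedEEG", function(object) {
  d <- dim(object@segments)
  if (length(d) != 3L)
    return("segments must be a 3-d array (channels x segments x samples)")
  if (d[1L] != length(object@channelLabels))
    return("first array extent must equal number of channel labels")
  TRUE
})

#' FeatureTensor: per-segment wavelet statistic vectors of one recording
#'
#' A channels x segments x features array of per-segment sub-band
#' statistics (24 features under defaults), with patient metadata carried
#' through from the source recording.
#'
#' @slot values Numeric array, channels x segments x features.
#' @slot featureNames Character vector naming the feature axis.
#' @slot channelLabels Character vector of channel names.
#' @slot age Patient age in years.
#' @slot label Integer class label or NA.
#' @slot recordingId Identifier string.
#'
#' @exportClass FeatureTensor
setClass("FeatureTensor",
  representation(
    values = "array",
    featureNames = "character",
    channelLabels = "character",
    age = "numeric",
    label = "integer",
    recordingId = "character"
  )
)

setValidity("FeatureTensor", function(object) {
  d <- dim(object@values)
  if (length(d) != 3L)
    return("values must be a 3-d array (channels x segments x features)")
  if (d[1L] != length(object@channelLabels))
    return("first array extent must equal number of channel labels")
  if (d[3L] != length(object@featureNames))
    return("third array extent must equal number of feature names")
  TRUE
})

#' EEGCohort: a list of recordings with class labels and ages
#'
#' @slot recordings List of [EEGRecording-class] objects.
#'
#' @exportClass EEGCohort
setClass("EEGCohort", representation(recordings = "list"))

setValidity("EEGCohort", function(object) {
  ok <- vapply(object@recordings, is, logical(1), "EEGRecording")
  if (!all(ok)) return("all cohort elements must be EEGRecording objects")
  TRUE
})

#' Construct an EEGCohort
#'
#' @param recordings List of [EEGRecording-class] objects.
#' @return An [EEGCohort-class].
#' @export
EEGCohort <- function(recordings = list()) {
  new("EEGCohort", recordings = recordings)
}

#' TrainedEEGModel: a fitted ensemble classifier with layout fingerprint
#'
#' @slot backend Backend id, `"gbdt"` (gradient-boosted trees, xgboost) or
#'   `"random_forest"` (ranger).
#' @slot fit The fitted backend object (opaque).
#' @slot featureNames Column names the model was trained on.
#' @slot fingerprint Hash of the feature layout; predictions are refused
#'   for rows with a different layout.
#' @slot spec The [modelSpec()] used for training.
#' @slot trainInfo List: seed, number of rows, class counts.
#'
#' @exportClass TrainedEEGModel
setClass("TrainedEEGModel",
  representation(
    backend = "character",
    fit = "ANY",
    featureNames = "character",
    fingerprint = "character",
    spec = "list",
    trainInfo = "list"
  )
)

## ---- accessors ----

#' @rdname eegpath-generics
#' @aliases channelLabels,EEGRecording-method
setMethod("channelLabels", "EEGRecording", function(x) x@channelLabels)
#' @rdname eegpath-generics
setMethod("channelLabels", "SegmentedEEG", function(x) x@channelLabels)
#' @rdname eegpath-generics
setMethod("channelLabels", "FeatureTensor", function(x) x@channelLabels)

#' @rdname eegpath-generics
setMethod("samplingRate", "EEGRecording", function(x) x@samplingRate)
#' @rdname eegpath-generics
setMethod("samplingRate", "SegmentedEEG", function(x) x@samplingRate)

#' @rdname eegpath-generics
setMethod("patientAge", "EEGRecording", function(x) x@age)
#' @rdname eegpath-generics
setMethod("patientAge", "SegmentedEEG", function(x) x@age)
#' @rdname eegpath-generics
setMethod("patientAge", "FeatureTensor", function(x) x@age)
#' @rdname eegpath-generics
setMethod("patientAge", "EEGCohort",
          function(x) vapply(x@recordings, patientAge, numeric(1)))

#' @rdname eegpath-generics
setMethod("classLabel", "EEGRecording", function(x) x@label)
#' @rdname eegpath-generics
setMethod("classLabel", "SegmentedEEG", function(x) x@label)
#' @rdname eegpath-generics
setMethod("classLabel", "FeatureTensor", function(x) x@label)
#' @rdname eegpath-generics
setMethod("classLabel", "EEGCohort",
          function(x) vapply(x@recordings, classLabel, integer(1)))

#' @rdname eegpath-generics
setMethod("recordingId", "EEGRecording", function(x) x@recordingId)
#' @rdname eegpath-generics
setMethod("recordingId", "SegmentedEEG", function(x) x@recordingId)
#' @rdname eegpath-generics
setMethod("recordingId", "FeatureTensor", function(x) x@recordingId)
#' @rdname eegpath-generics
setMethod("recordingId", "EEGCohort",
          function(x) vapply(x@recordings, recordingId, character(1)))

#' @rdname eegpath-generics
setMethod("signalMatrix", "EEGRecording", function(x) x@signal)

#' @rdname eegpath-generics
setMethod("featureValues", "FeatureTensor", function(x) x@values)

#' @rdname eegpath-generics
setMethod("featureNames", "FeatureTensor", function(x) x@featureNames)

#' @rdname eegpath-generics
setMethod("segmentArray", "SegmentedEEG", function(x) x@segments)

#' Number of recordings in a cohort
#' @param x An [EEGCohort-class].
#' @return Integer count.
#' @export
setMethod("length", "EEGCohort", function(x) length(x@recordings))

#' Extract one recording from a cohort
#' @param x An [EEGCohort-class].
#' @param i Index.
#' @return An [EEGRecording-class].
#' @export
setMethod("[[", "EEGCohort", function(x, i) x@recordings[[i]])

## ---- show methods ----

setMethod("show", "EEGRecording", function(object) {
  cat(sprintf(
    "EEGRecording '%s': %d channels x %d samples @ %g Hz (%.1f s)\n",
    object@recordingId, nrow(object@signal), ncol(object@signal),
    object@samplingRate, ncol(object@signal) / object@samplingRate))
  cat(sprintf("  age: %s  label: %s\n",
              format(object@age),
              if (is.na(object@label)) "NA"
              else c("normal", "pathological")[object@label + 1L]))
})

setMethod("show", "SegmentedEEG", function(object) {
  d <- dim(object@segments)
  cat(sprintf(
    "SegmentedEEG '%s': %d channels x %d segments x %d samples @ %g Hz\n",
    object@recordingId, d[1], d[2], d[3], object@samplingRate))
})

setMethod("show", "FeatureTensor", function(object) {
  d <- dim(object@values)
  cat(sprintf(
    "FeatureTensor '%s': %d channels x %d segments x %d features\n",
    object@recordingId, d[1], d[2], d[3]))
})

setMethod("show", "EEGCohort", function(object) {
  lab <- classLabel(object)
  cat(sprintf("EEGCohort: %d recordings (%d normal, %d pathological)\n",
              length(object@recordings),
              sum(lab == 0L, na.rm = TRUE), sum(lab == 1L, na.rm = TRUE)))
})

setMethod("show", "TrainedEEGModel", function(object) {
  cat(sprintf(
    "TrainedEEGModel (%s): %d features, fingerprint %s, trained on %d rows\n",
    object@backend, length(object@featureNames), object@fingerprint,
    object@trainInfo$nRows))
})
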