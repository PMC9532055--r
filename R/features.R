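## Per-segment statistical features of the selected wavelet sub-bands.
## Six statistics per sub-band: MV (mean), MAD (mean absolute deviation
## about the mean), SD, MAV (mean absolute value), skewness, kurtosis.

statNames <- c("mv", "mad", "sd", "mav", "skew", "kurt")

## Vectorized statistics over the columns of a coefficient matrix.
## Moment conventions: population SD by default; skewness g1 = m3/m2^1.5;
## kurtosis g2 = m4/m2^2 - 3 (excess).  Zero-variance columns get
## skewness = kurtosis = 0 so constant segments stay finite.
#' @noRd
statsMatrix <- function(M, sdConvention = "population",
                        excessKurtosis = TRUE) {
  m <- nrow(M)
  mv <- colMeans(M)
  centered <- sweep(M, 2L, mv)
  mad <- colMeans(abs(centered))
  m2 <- colMeans(centered^2)
  m3 <- colMeans(centered^3)
  m4 <- colMeans(centered^4)
  sdv <- if (sdConvention == "population" || m < 2L) {
    sqrt(m2)
  } else {
    sqrt(m2 * m / (m - 1))
  }
  mav <- colMeans(abs(M))
  zeroVar <- m2 <= 0
  skew <- ifelse(zeroVar, 0, m3 / m2^1.5)
  kurt <- ifelse(zeroVar, 0, m4 / m2^2 - if (excessKurtosis) 3 else 0)
  rbind(mv = mv, mad = mad, sd = sdv, mav = mav, skew = skew, kurt = kurt)
}

#' Six statistics of a coefficient sequence
#'
#' Mean (MV), mean absolute deviation about the mean
#' (MAD = (1/m) * sum(|x_i - u|)), standard deviation (SD, population by
#' default), mean absolute value (MAV), skewness and kurtosis
#' (moment-ratio estimators; kurtosis as excess by default).  For a
#' zero-variance input, skewness and kurtosis are defined as 0.
#'
#' @param x Numeric vector (length >= 1).
#' @param sdConvention `"population"` or `"sample"`.
#' @param excessKurtosis Report kurtosis as excess (default `TRUE`).
#' @return Named numeric vector `mv, mad, sd, mav, skew, kurt`.
#' @examples
#' computeStatistics(c(1, 2, 3))
#' @export
computeStatistics <- function(x, sdConvention = c("population", "sample"),
                              excessKurtosis = TRUE) {
  sdConvention <- match.arg(sdConvention)
  if (!is.numeric(x) || !length(x))
    stopf("input must be a non-empty numeric vector",
          class = "invalidInputError")
  drop(statsMatrix(matrix(x, ncol = 1L), sdConvention, excessKurtosis))
}

#' Z-score a feature vector
#'
#' Centers and scales the vector to zero mean and unit (population)
#' variance.  A zero-variance vector maps to all zeros rather than NaN.
#'
#' @param v Numeric vector, length >= 2.
#' @return The normalized vector.
#' @examples
#' normalizeVector(c(2, 4))
#' @export
normalizeVector <- function(v) {
  if (!is.numeric(v) || length(v) < 2L)
    stopf("vector of length >= 2 required", class = "invalidInputError")
  mu <- mean(v)
  s <- sqrt(mean((v - mu)^2))
  if (s <= 0) return(numeric(length(v)))
  (v - mu) / s
}

#' @noRd
featureNameVector <- function(config) {
  as.vector(vapply(config$selectedSubbands,
                   function(sb) paste0(statNames, "_", sb),
                   character(length(statNames))))
}

#' Feature vector of one segment
#'
#' Decomposes the segment ([dwtDecompose()]) and concatenates the six
#' statistics of each selected sub-band, in sub-band-major order
#' (`A5` block first under defaults, statistics ordered
#' `mv, mad, sd, mav, skew, kurt` within a block): 24 values under the
#' default configuration.
#'
#' @param segment Numeric vector (one channel, one window).
#' @param config A [waveletConfig()].
#' @param normalize Z-score the resulting vector (default `TRUE`).
#' @return Named numeric vector of length
#'   `6 * length(config$selectedSubbands)`.
#' @examples
#' length(featurizeSegment(rnorm(1250)))
#' @export
featurizeSegment <- function(segment, config = waveletConfig(),
                             normalize = TRUE) {
  co <- dwtDecompose(segment, config)
  v <- unlist(lapply(config$selectedSubbands, function(sb) {
    computeStatistics(co[[sb]], config$sdConvention, config$excessKurtosis)
  }), use.names = FALSE)
  names(v) <- featureNameVector(config)
  if (normalize) {
    nm <- names(v)
    v <- normalizeVector(v)
    names(v) <- nm
  }
  v
}

#' Feature tensor of a segmented recording
#'
#' Applies the wavelet feature extraction to every (channel, segment)
#' window and stacks the results into a channels x segments x features
#' array, carrying patient metadata through.  All windows are decomposed
#' in one vectorized pass.
#'
#' @param segRec A [SegmentedEEG-class].
#' @param config A [waveletConfig()].
#' @param normalize Per-vector z-scoring (default `TRUE`); set `FALSE`
#'   when cohort-level per-feature scaling is applied downstream.
#' @return A [FeatureTensor-class] with `F = 24` under defaults.
#' @export
featurizeRecording <- function(segRec, config = waveletConfig(),
                               normalize = TRUE) {
  stopifnot(is(segRec, "SegmentedEEG"), inherits(config, "WaveletConfig"))
  d <- dim(segRec@segments)
  C <- d[1]; S <- d[2]; L <- d[3]
  ## time x (C*S) matrix: column index runs channel-fastest
  X <- matrix(aperm(segRec@segments, c(3, 1, 2)), nrow = L)
  co <- dwtMatrix(X, config)
  blocks <- lapply(config$selectedSubbands, function(sb) {
    statsMatrix(co[[sb]], config$sdConvention, config$excessKurtosis)
  })
  feat <- do.call(rbind, blocks)        # (F) x (C*S), feature-major rows
  if (normalize) {
    mu <- colMeans(feat)
    s <- sqrt(colMeans(feat^2) - mu^2)
    s[s <= 0] <- Inf                    # zero-variance vector -> zeros
    feat <- sweep(sweep(feat, 2L, mu), 2L, s, "/")
  }
  FF <- nrow(feat)
  values <- aperm(array(feat, dim = c(FF, C, S)), c(2, 3, 1))
  new("FeatureTensor", values = values,
      featureNames = featureNameVector(config),
      channelLabels = segRec@channelLabels,
      age = segRec@age, label = segRec@label,
      recordingId = segRec@recordingId)
}

#' Feature tensors for a whole cohort
#'
#' Preprocesses ([preprocessRecording()]) and featurizes every recording.
#' Normalization scope: `"per_vector"` (default) z-scores each 24-value
#' segment vector independently; `"per_feature"` scales each feature index
#' to zero mean/unit variance across all channels, segments and
#' recordings of the cohort; `"none"` skips scaling.
#'
#' @param cohort An [EEGCohort-class].
#' @param montage Ordered electrode names.
#' @param targetRate Analysis rate in Hz.
#' @param windowSeconds,nSegments,policy Passed to [segmentRecording()].
#' @param config A [waveletConfig()].
#' @param normalizationScope `"per_vector"`, `"per_feature"` or `"none"`.
#' @return List of [FeatureTensor-class] objects, one per recording.
#' @export
featurizeCohort <- function(cohort, montage = standardMontage21(),
                            targetRate = 250, windowSeconds = 5,
                            nSegments = 100,
                            policy = c("strict", "available"),
                            config = waveletConfig(),
                            normalizationScope = c("per_vector",
                                                   "per_feature", "none")) {
  policy <- match.arg(policy)
  normalizationScope <- match.arg(normalizationScope)
  tensors <- lapply(seq_len(length(cohort)), function(i) {
    seg <- preprocessRecording(cohort[[i]], montage, targetRate,
                               windowSeconds, nSegments, policy)
    featurizeRecording(seg, config,
                       normalize = normalizationScope == "per_vector")
  })
  if (normalizationScope == "per_feature") {
    FF <- dim(tensors[[1]]@values)[3]
    pooled <- do.call(rbind, lapply(tensors, function(tt) {
      matrix(tt@values, ncol = FF)
    }))
    mu <- colMeans(pooled)
    s <- colPopSd(pooled)
    s[s <= 0] <- Inf
    tensors <- lapply(tensors, function(tt) {
      v <- tt@values
      for (f in seq_len(FF)) v[, , f] <- (v[, , f] - mu[f]) / s[f]
      tt@values <- v
      tt
    })
  }
  tensors
}
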