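## Multilevel discrete wavelet transform (pyramid algorithm) with
## half-sample symmetric boundary extension.  Filter bank coefficients are
## the standard orthogonal Symlet family values; only sym6 (the default
## wavelet of the pipeline) is shipped.  Conventions match the common
## "symmetric" mode of wavelet toolkits: a length-L input yields
## floor((L + filterLength - 1) / 2) coefficients per branch.

#' Wavelet decomposition/reconstruction filters
#'
#' @param waveletName Wavelet family member; only `"sym6"` is available.
#' @return List with `decLo`, `decHi`, `recLo`, `recHi` filter vectors and
#'   `length` (number of taps).
#' @export
waveletFilters <- function(waveletName = "sym6") {
  if (!identical(waveletName, "sym6"))
    stopf("unknown wavelet '%s' (only sym6 is shipped)", waveletName,
          class = "invalidConfigError")
  decLo <- c(
     0.015404109327027373,  0.0034907120842174702, -0.11799011114819057,
    -0.048311742585633,     0.4910559419267466,     0.787641141030194,
     0.3379294217276218,   -0.07263752278646252,   -0.021060292512300564,
     0.04472490177066578,   0.0017677118642428036, -0.007800708325034148)
  n <- length(decLo)
  ## quadrature mirror: decHi[k] = (-1)^(k+1) * decLo[n-1-k] (0-based)
  decHi <- rev(decLo) * (-1)^seq_len(n)
  list(decLo = decLo, decHi = decHi,
       recLo = rev(decLo), recHi = rev(decHi), length = n)
}

#' Wavelet analysis configuration
#'
#' @param waveletName Mother wavelet (default `"sym6"`).
#' @param levels Decomposition depth (default 5).
#' @param selectedSubbands Ordered sub-band names whose statistics form the
#'   feature vector; default `c("A5", "D5", "D4", "D3")`, the approximation
#'   plus the three details covering roughly 2-31 Hz at 250 Hz — the
#'   delta/theta/alpha/beta rhythms that carry most diagnostic content.
#' @param extensionMode Boundary handling; only `"symmetric"` (half-sample
#'   symmetric padding) is implemented.
#' @param sdConvention `"population"` (divide by m) or `"sample"` for the
#'   SD feature and z-scoring.
#' @param excessKurtosis If `TRUE` (default) kurtosis is reported as excess
#'   (Gaussian baseline 0).
#' @return A validated `WaveletConfig` list.
#' @export
waveletConfig <- function(waveletName = "sym6", levels = 5L,
                          selectedSubbands = c("A5", "D5", "D4", "D3"),
                          extensionMode = "symmetric",
                          sdConvention = c("population", "sample"),
                          excessKurtosis = TRUE) {
  sdConvention <- match.arg(sdConvention)
  if (levels < 1L)
    stopf("levels must be >= 1", class = "invalidConfigError")
  if (!identical(extensionMode, "symmetric"))
    stopf("only symmetric extension is implemented",
          class = "invalidConfigError")
  valid <- c(paste0("A", levels), paste0("D", seq_len(levels)))
  if (!all(selectedSubbands %in% valid))
    stopf("selectedSubbands must be drawn from {%s}",
          paste(valid, collapse = ", "), class = "invalidConfigError")
  structure(list(
    waveletName = waveletName, levels = as.integer(levels),
    selectedSubbands = selectedSubbands, extensionMode = extensionMode,
    sdConvention = sdConvention, excessKurtosis = excessKurtosis
  ), class = "WaveletConfig")
}

## Symmetric (half-sample) extension of the rows of a time x series
## matrix by p samples each side; the edge sample is repeated.  Handles
## signals shorter than the pad by repeated reflection.
#' @noRd
symExtendIdx <- function(n, p) {
  idx <- seq.int(1L - p, n + p)
  period <- 2L * n
  idx <- ((idx - 1L) %% period + period) %% period  # 0-based, in [0, 2n)
  idx <- ifelse(idx >= n, 2L * n - 1L - idx, idx)
  idx + 1L
}

## One analysis step on a matrix X (time in rows, one series per column):
## symmetric-extend, convolve with both filters, downsample.  The
## convolve-and-downsample is expressed as one sparse analysis operator
## applied to X, folding the boundary extension into the column indices;
## this keeps the per-level cost at outLen x filterLength multiply-adds
## per series.
#' @noRd
dwtStepMatrix <- function(X, filt) {
  n <- nrow(X); fl <- filt$length
  outLen <- (n + fl - 1L) %/% 2L
  extIdx <- symExtendIdx(n, fl - 1L)
  ## output k (1-based) is full-convolution sample fl + 2k - 1, i.e.
  ## sum_j f[j] * ext[fl - j + 2k]; map ext positions back to rows of X
  k <- rep(seq_len(outLen), each = fl)
  j <- rep(seq_len(fl), times = outLen)
  cols <- extIdx[fl - j + 2L * k]
  opLo <- Matrix::sparseMatrix(i = k, j = cols, x = filt$decLo[j],
                               dims = c(outLen, n))
  opHi <- Matrix::sparseMatrix(i = k, j = cols, x = filt$decHi[j],
                               dims = c(outLen, n))
  dense <- function(m) matrix(m@x, m@Dim[1], m@Dim[2])
  list(a = dense(opLo %*% X), d = dense(opHi %*% X))
}

## Multilevel analysis of a matrix of equal-length series (columns).
## Returns coefficient matrices named A<levels>, D<levels>..D1.
#' @noRd
dwtMatrix <- function(X, config) {
  filt <- waveletFilters(config$waveletName)
  minLen <- filt$length
  out <- list()
  a <- X
  for (lev in seq_len(config$levels)) {
    if (nrow(a) < minLen)
      stopf("segment too short (%d samples) for %d-level decomposition",
            nrow(X), config$levels, class = "decompositionError")
    step <- dwtStepMatrix(a, filt)
    out[[paste0("D", lev)]] <- step$d
    a <- step$a
  }
  out[[paste0("A", config$levels)]] <- a
  ## order: A_n, D_n, ..., D_1
  out[c(paste0("A", config$levels), paste0("D", config$levels:1))]
}

#' Multilevel DWT of one segment
#'
#' Decomposes a single-channel segment into `levels + 1` sub-band
#' coefficient sequences: the approximation `A<levels>` and details
#' `D<levels>` down to `D1`.
#'
#' @param segment Numeric vector.
#' @param config A [waveletConfig()].
#' @return Named list of coefficient vectors, ordered
#'   `A<levels>, D<levels>, ..., D1`.
#' @examples
#' co <- dwtDecompose(sin(seq_len(1250) / 10), waveletConfig())
#' lengths(co)
#' @export
dwtDecompose <- function(segment, config = waveletConfig()) {
  stopifnot(inherits(config, "WaveletConfig"))
  if (!is.numeric(segment) || !length(segment))
    stopf("segment must be a non-empty numeric vector",
          class = "invalidInputError")
  lapply(dwtMatrix(matrix(segment, ncol = 1L), config), drop)
}

## One synthesis step: upsample both branches, convolve with the
## reconstruction filters, sum, and trim to the standard output length
## 2*length(a) - filterLength + 2 starting at offset filterLength - 2.
#' @noRd
idwtStep <- function(a, d, filt) {
  la <- length(a)
  up <- function(c) { u <- numeric(2L * la); u[seq(1L, 2L * la, 2L)] <- c; u }
  full <- function(x, f) {
    out <- numeric(length(x) + filt$length - 1L)
    for (j in seq_len(filt$length)) {
      rows <- j:(j + length(x) - 1L)
      out[rows] <- out[rows] + f[j] * x
    }
    out
  }
  s <- full(up(a), filt$recLo) + full(up(d), filt$recHi)
  outLen <- 2L * la - filt$length + 2L
  s[(filt$length - 1L):(filt$length - 2L + outLen)]
}

#' Inverse multilevel DWT
#'
#' Reconstructs a segment from the full coefficient set produced by
#' [dwtDecompose()].  Intermediate lengths are re-derived from
#' `originalLength`, so reconstruction is exact (to round-off) for any
#' input length.
#'
#' @param coefficients Named list from [dwtDecompose()] (all sub-bands).
#' @param config The [waveletConfig()] used for decomposition.
#' @param originalLength Length of the original segment.
#' @return Numeric vector of length `originalLength`.
#' @export
dwtReconstruct <- function(coefficients, config, originalLength) {
  filt <- waveletFilters(config$waveletName)
  ## lengths at each level of the analysis cascade
  lens <- integer(config$levels)
  n <- originalLength
  for (lev in seq_len(config$levels)) {
    n <- (n + filt$length - 1L) %/% 2L
    lens[lev] <- n
  }
  a <- coefficients[[paste0("A", config$levels)]]
  for (lev in rev(seq_len(config$levels))) {
    d <- coefficients[[paste0("D", lev)]]
    targetLen <- if (lev > 1L) lens[lev - 1L] else originalLength
    a <- idwtStep(a, d, filt)[seq_len(targetLen)]
  }
  a
}

#' Frequency range of a DWT sub-band
#'
#' For detail level n at sampling rate sf, the band is
#' (sf / 2^(n+1), sf / 2^n) Hz; the approximation at level n covers
#' (0, sf / 2^(n+1)).
#'
#' @param level Decomposition level (>= 1).
#' @param samplingRate Sampling rate in Hz.
#' @param type `"detail"` or `"approximation"`.
#' @return Numeric `c(low, high)` in Hz.
#' @examples
#' subbandFrequencyRange(5, 250)                  # D5: 3.90625-7.8125 Hz
#' subbandFrequencyRange(5, 250, "approximation") # A5: 0-3.90625 Hz
#' @export
subbandFrequencyRange <- function(level, samplingRate,
                                  type = c("detail", "approximation")) {
  type <- match.arg(type)
  if (level < 1L)
    stopf("level must be >= 1", class = "invalidConfigError")
  assertPositiveScalar(samplingRate, "samplingRate")
  if (type == "detail") {
    c(samplingRate / 2^(level + 1), samplingRate / 2^level)
  } else {
    c(0, samplingRate / 2^(level + 1))
  }
}
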