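#' Restrict a recording to a montage, in montage order
#'
#' Matches channels by normalized label ([normalizeChannelLabels()]), drops
#' channels outside the montage, and reorders the rest to montage order.
#' Clinical archives mix montages of 21-31 channels; this standardizes
#' every recording to the same ordered channel set.
#'
#' @param recording An [EEGRecording-class].
#' @param montage Ordered electrode names; default [standardMontage21()].
#' @return An [EEGRecording-class] with channels exactly in montage order.
#' @examples
#' cfg <- synthConfig(duration = 5)
#' rec <- generateRecording(cfg, 0, 30, seed = 1)
#' channelLabels(selectChannels(rec, c("O1", "CZ")))
#' @export
selectChannels <- function(recording, montage = standardMontage21()) {
  have <- normalizeChannelLabels(channelLabels(recording))
  want <- normalizeChannelLabels(montage)
  idx <- match(want, have)
  if (anyNA(idx)) {
    stopf("recording is missing montage channel(s): %s",
          paste(montage[is.na(idx)], collapse = ", "),
          class = "missingChannelError")
  }
  EEGRecording(signalMatrix(recording)[idx, , drop = FALSE],
               want,
               samplingRate(recording),
               age = patientAge(recording),
               label = classLabel(recording),
               recordingId = recordingId(recording))
}

#' Resample a recording to a target rate
#'
#' Polyphase rational resampling with an anti-aliasing FIR low-pass
#' (via the signal package).  A recording already at the target rate is
#' returned unchanged.  The output sample count is
#' `floor(samples * targetRate / samplingRate)`.
#'
#' @param recording An [EEGRecording-class].
#' @param targetRate Target sampling rate in Hz (default 250).
#' @return The resampled [EEGRecording-class].
#' @export
resampleRecording <- function(recording, targetRate = 250) {
  if (!is.numeric(targetRate) || targetRate <= 0)
    stopf("targetRate must be positive", class = "invalidConfigError")
  rate <- samplingRate(recording)
  if (isTRUE(all.equal(rate, targetRate))) return(recording)

  ## reduce targetRate/rate to an integer ratio p/q
  toInt <- function(x) {
    f <- 1
    while (abs(x * f - round(x * f)) > 1e-9 && f < 1e6) f <- f * 10
    round(x * f)
  }
  scaleF <- 1
  while (abs(targetRate * scaleF - round(targetRate * scaleF)) > 1e-9 ||
         abs(rate * scaleF - round(rate * scaleF)) > 1e-9) {
    scaleF <- scaleF * 10
    if (scaleF > 1e6)
      stopf("cannot express rate ratio %g/%g as a rational factor",
            targetRate, rate, class = "invalidConfigError")
  }
  p <- round(targetRate * scaleF); q <- round(rate * scaleF)
  g <- gcdInt(p, q); p <- p %/% g; q <- q %/% g

  sig <- signalMatrix(recording)
  nOut <- floor(ncol(sig) * targetRate / rate)
  ## upfirdn: zero-stuff by p, anti-aliasing FIR low-pass at the tighter
  ## of the two Nyquist limits, compensate the group delay, keep every
  ## q-th sample
  nTaps <- 20L * max(p, q) + 1L
  h <- p * signal::fir1(nTaps - 1L, 1 / max(p, q))
  delay <- (nTaps - 1L) %/% 2L
  out <- matrix(0, nrow(sig), nOut)
  for (ch in seq_len(nrow(sig))) {
    x <- sig[ch, ]
    up <- numeric(length(x) * p)
    up[seq(1L, by = p, length.out = length(x))] <- x
    ## symmetric padding absorbs the filter edge transient
    pad <- min(delay, length(up))
    upPad <- c(rev(up[seq_len(pad)]), up, rev(up[length(up) - seq_len(pad) + 1L]))
    y <- stats::filter(upPad, h, method = "convolution", sides = 1L)
    y <- y[!is.na(y)]
    y <- y[pad + delay - (nTaps - 1L) + seq(1L, by = q, length.out = nOut)]
    out[ch, ] <- y
  }
  EEGRecording(out, channelLabels(recording), targetRate,
               age = patientAge(recording), label = classLabel(recording),
               recordingId = recordingId(recording))
}

#' @noRd
gcdInt <- function(a, b) {
  while (b != 0) { t <- b; b <- a %% b; a <- t }
  a
}

#' Cut a recording into equal non-overlapping windows
#'
#' Segments each channel from time zero into consecutive windows of
#' `windowSeconds`, discarding the trailing remainder.  Under the strict
#' policy exactly `nSegments` windows are required and taken (the default
#' protocol: 100 five-second slices of 1250 samples at 250 Hz); under the
#' available policy all full windows are taken, which lets short recordings
#' exercise the pipeline.
#'
#' @param recording An [EEGRecording-class] at the analysis rate.
#' @param windowSeconds Window length in seconds (default 5).
#' @param nSegments Number of windows required under the strict policy
#'   (default 100).
#' @param policy `"strict"` or `"available"`.
#' @return A [SegmentedEEG-class].
#' @examples
#' rec <- generateRecording(synthConfig(duration = 12), 0, 30, seed = 2)
#' seg <- segmentRecording(rec, policy = "available")
#' dim(segmentArray(seg))
#' @export
segmentRecording <- function(recording, windowSeconds = 5, nSegments = 100,
                             policy = c("strict", "available")) {
  policy <- match.arg(policy)
  rate <- samplingRate(recording)
  segLen <- as.integer(round(windowSeconds * rate))
  if (segLen <= 0)
    stopf("windowSeconds x samplingRate must be positive",
          class = "invalidConfigError")
  sig <- signalMatrix(recording)
  nAvail <- ncol(sig) %/% segLen
  if (policy == "strict") {
    if (nAvail < nSegments)
      stopf(paste0("recording too short: %d full windows available, ",
                   "%d required"), nAvail, nSegments,
            class = "insufficientDataError")
    S <- as.integer(nSegments)
  } else {
    if (nAvail < 2L)
      stopf("recording too short: at least 2 full windows needed",
            class = "insufficientDataError")
    S <- as.integer(nAvail)
  }
  C <- nrow(sig)
  used <- sig[, seq_len(S * segLen), drop = FALSE]
  ## channels x samples -> channels x segments x segment_length
  segs <- aperm(array(used, dim = c(C, segLen, S)), c(1, 3, 2))
  new("SegmentedEEG", segments = segs,
      channelLabels = channelLabels(recording),
      samplingRate = rate, age = patientAge(recording),
      label = classLabel(recording), recordingId = recordingId(recording))
}

#' Full preprocessing of one recording
#'
#' Channel selection, resampling and segmentation in one call.
#'
#' @inheritParams selectChannels
#' @inheritParams segmentRecording
#' @param targetRate Analysis sampling rate in Hz.
#' @return A [SegmentedEEG-class].
#' @export
preprocessRecording <- function(recording, montage = standardMontage21(),
                                targetRate = 250, windowSeconds = 5,
                                nSegments = 100,
                                policy = c("strict", "available")) {
  policy <- match.arg(policy)
  rec <- selectChannels(recording, montage)
  rec <- resampleRecording(rec, targetRate)
  segmentRecording(rec, windowSeconds, nSegments, policy)
}
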