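#' Configuration for the synthetic EEG generator
#'
#' The generator emulates the gross properties of clinical scalp EEG
#' archives used for pathology screening: 21-channel 10-20 montage
#' recordings of at least several hundred seconds at 250 Hz, with a
#' per-recording patient age, and class-dependent spectral structure.
#' Normal recordings are 1/f ("pink") background activity plus a ~10 Hz
#' alpha rhythm; pathological recordings additionally carry boosted
#' delta-band (< 4 Hz) power and intermittent spike-and-slow-wave bursts
#' concentrated on a focal channel subset.
#'
#' @param nChannels Number of channels; must match `length(channelLabels)`.
#' @param channelLabels Channel names; defaults to [standardMontage21()].
#' @param samplingRate Sampling rate in Hz.
#' @param duration Recording length in seconds.
#' @param ageRange Length-2 numeric, uniform age range in years.
#' @param abnormalDeltaGain Power multiplier applied to sub-4 Hz content in
#'   the pathological class (dimensionless, > 0).
#' @param burstRate Spike-and-slow-wave bursts per minute in the
#'   pathological class.
#' @param focalChannels Channels receiving the bursts (left
#'   central/parietal/occipital by default, a common focal distribution).
#' @param backgroundSd Background amplitude scale in µV.
#' @param alphaAmplitude Amplitude of the ~10 Hz rhythm in µV.
#' @param burstAmplitude Peak amplitude of the spike component in µV.
#' @param ageShift Years added to pathological-class ages (0 by default so
#'   the two classes share one age distribution and age carries no label
#'   information; set non-zero to exercise the age-fusion effect).
#' @param seed Integer master seed for the cohort.
#' @return A validated `SynthConfig` list.
#' @examples
#' cfg <- synthConfig(duration = 20)
#' @export
synthConfig <- function(nChannels = 21L,
                        channelLabels = standardMontage21(),
                        samplingRate = 250,
                        duration = 520,
                        ageRange = c(1, 90),
                        abnormalDeltaGain = 3,
                        burstRate = 6,
                        focalChannels = c("C3", "P3", "O1"),
                        backgroundSd = 15,
                        alphaAmplitude = 5,
                        burstAmplitude = 40,
                        ageShift = 0,
                        seed = 1L) {
  assertPositiveScalar(samplingRate, "samplingRate")
  assertPositiveScalar(duration, "duration")
  assertPositiveScalar(abnormalDeltaGain, "abnormalDeltaGain")
  assertPositiveScalar(backgroundSd, "backgroundSd")
  if (burstRate < 0)
    stopf("'burstRate' must be non-negative", class = "invalidConfigError")
  if (length(channelLabels) != nChannels)
    stopf("nChannels (%d) must equal length(channelLabels) (%d)",
          nChannels, length(channelLabels), class = "invalidConfigError")
  if (length(ageRange) != 2L || ageRange[1] > ageRange[2] || ageRange[1] < 0)
    stopf("'ageRange' must be a non-decreasing non-negative pair",
          class = "invalidConfigError")
  structure(list(
    nChannels = as.integer(nChannels),
    channelLabels = as.character(channelLabels),
    samplingRate = samplingRate,
    duration = duration,
    ageRange = ageRange,
    abnormalDeltaGain = abnormalDeltaGain,
    burstRate = burstRate,
    focalChannels = focalChannels,
    backgroundSd = backgroundSd,
    alphaAmplitude = alphaAmplitude,
    burstAmplitude = burstAmplitude,
    ageShift = ageShift,
    seed = as.integer(seed)
  ), class = "SynthConfig")
}

## One spike-and-slow-wave burst kernel: a sharp ~70 ms biphasic transient
## followed by a ~350 ms slow half-wave.  Returned in units of the peak
## amplitude (max |kernel| = 1).
#' @noRd
spikeWaveKernel <- function(samplingRate) {
  spikeLen <- max(3L, round(0.07 * samplingRate))
  slowLen <- max(5L, round(0.35 * samplingRate))
  tSpike <- seq(0, 1, length.out = spikeLen)
  spike <- sin(pi * tSpike)^3            # sharp positive transient
  tSlow <- seq(0, pi, length.out = slowLen)
  slow <- -0.6 * sin(tSlow)              # slow negative half-wave
  k <- c(spike, slow)
  k / max(abs(k))
}

#' Generate one synthetic EEG recording
#'
#' Deterministic given `(config, label, age, seed)`: the same arguments
#' always produce bit-identical signal matrices.  Normal recordings are
#' pink (1/f-power) background noise with a 10 Hz oscillation; pathological
#' recordings additionally have their sub-4 Hz spectral amplitude scaled by
#' `sqrt(abnormalDeltaGain)` and spike-and-slow-wave bursts inserted at
#' `burstRate` per minute on the focal channels.
#'
#' @param config A [synthConfig()].
#' @param label Class label: 0 normal, 1 pathological.
#' @param age Patient age in years.
#' @param seed Integer seed for this recording.
#' @param recordingId Identifier string.
#' @return An [EEGRecording-class].
#' @examples
#' rec <- generateRecording(synthConfig(duration = 10), label = 1,
#'                          age = 40, seed = 7)
#' dim(signalMatrix(rec))
#' @export
generateRecording <- function(config, label, age, seed,
                              recordingId = sprintf("synth-%d", seed)) {
  stopifnot(inherits(config, "SynthConfig"))
  if (!label %in% c(0, 1))
    stopf("label must be 0 or 1", class = "invalidConfigError")
  n <- as.integer(round(config$duration * config$samplingRate))
  if (n <= 0)
    stopf("duration x samplingRate must be positive",
          class = "invalidConfigError")
  C <- config$nChannels
  rate <- config$samplingRate

  oldSeed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(oldSeed)) assign(".Random.seed", oldSeed, globalenv()))
  set.seed(as.integer(seed))

  ## Frequency axis of the length-n DFT (two-sided).
  freq <- c(seq_len(ceiling(n / 2 + 1)) - 1, -rev(seq_len(floor((n - 1) / 2))))
  freq <- abs(freq) * rate / n
  ## Pink-noise amplitude shaping: power ~ 1/f, floored at 0.5 Hz so the
  ## DC region stays bounded.
  shape <- 1 / sqrt(pmax(freq, 0.5))
  if (label == 1) {
    ## Pathological class: boost delta-band (< 4 Hz) power.
    deltaIdx <- freq > 0 & freq < 4
    shape[deltaIdx] <- shape[deltaIdx] * sqrt(config$abnormalDeltaGain)
  }
  shape[1] <- 0  # remove DC

  sig <- matrix(0, C, n)
  tAxis <- (seq_len(n) - 1) / rate
  for (ch in seq_len(C)) {
    ## white complex spectrum shaped to the target amplitude profile;
    ## the real part of its inverse DFT is Gaussian noise with power ~ shape^2
    z <- complex(real = rnorm(n), imaginary = rnorm(n))
    x <- Re(fft(z * shape, inverse = TRUE)) / n
    x <- x / sqrt(mean(x^2)) * config$backgroundSd
    phase <- runif(1, 0, 2 * pi)
    aFreq <- 10 + runif(1, -0.5, 0.5)
    x <- x + config$alphaAmplitude * sin(2 * pi * aFreq * tAxis + phase)
    sig[ch, ] <- x
  }

  if (label == 1 && config$burstRate > 0) {
    kernel <- spikeWaveKernel(rate)
    nBursts <- max(1L, round(config$burstRate * config$duration / 60))
    focalIdx <- which(config$channelLabels %in% config$focalChannels)
    if (!length(focalIdx)) focalIdx <- seq_len(min(3L, C))
    starts <- sort(sample.int(max(1L, n - length(kernel)), nBursts,
                              replace = TRUE))
    for (s in starts) {
      idx <- s:(s + length(kernel) - 1L)
      amp <- config$burstAmplitude * runif(1, 0.7, 1.3)
      for (ch in focalIdx) {
        sig[ch, idx] <- sig[ch, idx] + amp * runif(1, 0.8, 1.2) * kernel
      }
    }
  }

  EEGRecording(sig, config$channelLabels, rate, age = age,
               label = as.integer(label), recordingId = recordingId)
}

#' Generate a seeded synthetic cohort
#'
#' Per-recording seeds are derived deterministically from `config$seed`, so
#' two calls with the same configuration give bit-identical cohorts.  Ages
#' are drawn uniformly from `config$ageRange` for both classes (plus
#' `config$ageShift` for the pathological class when set).  Normal
#' recordings come first, then pathological.
#'
#' @param config A [synthConfig()].
#' @param nNormal Number of normal recordings.
#' @param nAbnormal Number of pathological recordings.
#' @return An [EEGCohort-class] with `nNormal + nAbnormal` recordings.
#' @examples
#' coh <- generateCohort(synthConfig(duration = 10), 2, 2)
#' classLabel(coh)
#' @export
generateCohort <- function(config, nNormal, nAbnormal) {
  stopifnot(inherits(config, "SynthConfig"))
  if (nNormal < 0 || nAbnormal < 0)
    stopf("cohort counts must be non-negative", class = "invalidConfigError")
  nTotal <- nNormal + nAbnormal
  labels <- c(rep(0L, nNormal), rep(1L, nAbnormal))

  oldSeed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(oldSeed)) assign(".Random.seed", oldSeed, globalenv()))
  set.seed(deriveSeed(config$seed, 0L))
  ages <- runif(nTotal, config$ageRange[1], config$ageRange[2])
  ages <- ages + ifelse(labels == 1L, config$ageShift, 0)

  recs <- vector("list", nTotal)
  for (i in seq_len(nTotal)) {
    recs[[i]] <- generateRecording(
      config, labels[i], ages[i], seed = deriveSeed(config$seed, i),
      recordingId = sprintf("synth-%03d-%s", i,
                            c("norm", "path")[labels[i] + 1L]))
  }
  EEGCohort(recs)
}

#' Generate and featurize a synthetic cohort one recording at a time
#'
#' Equivalent to `featurizeCohort(generateCohort(config, nNormal,
#' nAbnormal), ...)` — same seeds, same ages, bit-identical features —
#' but each raw recording is discarded as soon as its feature tensor is
#' built, so full-length cohorts of hundreds of recordings fit in a few
#' hundred megabytes instead of gigabytes.
#'
#' @param config A [synthConfig()].
#' @param nNormal,nAbnormal Class counts.
#' @param montage,targetRate,windowSeconds,nSegments,policy Passed to
#'   [preprocessRecording()].
#' @param waveletCfg A [waveletConfig()].
#' @param normalize Per-vector z-scoring (default `TRUE`).
#' @return List of [FeatureTensor-class] objects.
#' @export
synthesizeFeatureTensors <- function(config, nNormal, nAbnormal,
                                     montage = standardMontage21(),
                                     targetRate = 250, windowSeconds = 5,
                                     nSegments = 100,
                                     policy = c("strict", "available"),
                                     waveletCfg = waveletConfig(),
                                     normalize = TRUE) {
  stopifnot(inherits(config, "SynthConfig"))
  policy <- match.arg(policy)
  nTotal <- nNormal + nAbnormal
  labels <- c(rep(0L, nNormal), rep(1L, nAbnormal))

  oldSeed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(oldSeed)) assign(".Random.seed", oldSeed, globalenv()))
  set.seed(deriveSeed(config$seed, 0L))
  ages <- runif(nTotal, config$ageRange[1], config$ageRange[2])
  ages <- ages + ifelse(labels == 1L, config$ageShift, 0)

  lapply(seq_len(nTotal), function(i) {
    rec <- generateRecording(
      config, labels[i], ages[i], seed = deriveSeed(config$seed, i),
      recordingId = sprintf("synth-%03d-%s", i,
                            c("norm", "path")[labels[i] + 1L]))
    seg <- preprocessRecording(rec, montage, targetRate, windowSeconds,
                               nSegments, policy)
    featurizeRecording(seg, waveletCfg, normalize = normalize)
  })
}

#' Mean band power of a recording
#'
#' Average periodogram power of all channels within a frequency band, used
#' to verify the class-dependent spectral structure of synthetic cohorts.
#'
#' @param recording An [EEGRecording-class].
#' @param band Length-2 numeric band (Hz), e.g. `c(0, 4)` for delta.
#' @return Mean power (µV²) across channels within the band.
#' @export
bandPower <- function(recording, band = c(0, 4)) {
  sig <- signalMatrix(recording)
  rate <- samplingRate(recording)
  n <- ncol(sig)
  freq <- (seq_len(floor(n / 2)) - 1) * rate / n
  sel <- freq >= band[1] & freq < band[2]
  pw <- vapply(seq_len(nrow(sig)), function(ch) {
    p <- Mod(fft(sig[ch, ]))^2 / n
    mean(p[seq_len(floor(n / 2))][sel])
  }, numeric(1))
  mean(pw)
}
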