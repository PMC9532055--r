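## Minimal EDF (European Data Format) writer/reader for continuous
## multichannel recordings: 256-byte fixed header + 256 bytes per signal,
## then 16-bit little-endian data records of one second each.  Enough to
## round-trip the synthetic cohorts and to ingest plain clinical EDF
## exports; EDF+ annotation channels are not interpreted.

#' @noRd
padField <- function(x, width) {
  s <- substr(as.character(x), 1L, width)
  formatC(s, width = width, flag = "-")
}

#' @noRd
numField <- function(x, width) {
  s <- formatC(x, format = "g", digits = width - 2, width = 1)
  if (nchar(s) > width) s <- substr(s, 1L, width)
  padField(s, width)
}

#' Write a recording to an EDF file
#'
#' Signals are quantized to 16 bits against per-channel physical ranges.
#' Only whole seconds are written (one data record per second); a trailing
#' sub-second remainder is dropped.  The sampling rate must be a positive
#' integer.
#'
#' @param recording An [EEGRecording-class].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @seealso [readEDF()]
#' @export
writeEDF <- function(recording, path) {
  sig <- signalMatrix(recording)
  rate <- samplingRate(recording)
  if (rate != round(rate) || rate <= 0)
    stopf("EDF writing requires a positive integer sampling rate",
          class = "invalidConfigError")
  rate <- as.integer(rate)
  nRecords <- ncol(sig) %/% rate
  if (nRecords < 1L)
    stopf("recording shorter than one EDF data record (1 s)",
          class = "insufficientDataError")
  ns <- nrow(sig)
  sig <- sig[, seq_len(nRecords * rate), drop = FALSE]

  physMin <- apply(sig, 1, min)
  physMax <- apply(sig, 1, max)
  flat <- physMax - physMin < 1e-12
  physMin[flat] <- physMin[flat] - 1
  physMax[flat] <- physMax[flat] + 1
  digMin <- -32768; digMax <- 32767

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    padField("0", 8),
    padField(recordingId(recording), 80),
    padField(sprintf("age=%s label=%s", format(patientAge(recording)),
                     format(classLabel(recording))), 80),
    "01.01.00", "00.00.00",
    padField(256L * (1L + ns), 8),
    padField("", 44),
    padField(nRecords, 8),
    padField(1L, 8),
    padField(ns, 4)
  )
  writeChar(hdr, con, nchars = nchar(hdr), eos = NULL)
  fields <- c(
    vapply(channelLabels(recording),
           function(l) padField(paste("EEG", l), 16), ""),
    rep(padField("", 80), ns),
    rep(padField("uV", 8), ns),
    vapply(physMin, numField, "", width = 8),
    vapply(physMax, numField, "", width = 8),
    rep(padField(digMin, 8), ns),
    rep(padField(digMax, 8), ns),
    rep(padField("", 80), ns),
    rep(padField(rate, 8), ns),
    rep(padField("", 32), ns)
  )
  sHdr <- paste(fields, collapse = "")
  writeChar(sHdr, con, nchars = nchar(sHdr), eos = NULL)

  scale <- (digMax - digMin) / (physMax - physMin)
  for (r in seq_len(nRecords)) {
    idx <- ((r - 1L) * rate + 1L):(r * rate)
    block <- vapply(seq_len(ns), function(ch) {
      as.integer(round((sig[ch, idx] - physMin[ch]) * scale[ch]) + digMin)
    }, integer(rate))
    writeBin(as.integer(block), con, size = 2L, endian = "little")
  }
  invisible(path)
}

#' Read an EDF file into an EEGRecording
#'
#' Reads a plain continuous EDF file with equal per-signal sampling rates.
#' Channel labels are returned as stored (use [normalizeChannelLabels()] or
#' [selectChannels()] to map them onto the montage).  Age and class label
#' are taken from the arguments when given, else recovered from the
#' `age=... label=...` convention [writeEDF()] stores in the recording-id
#' header field, else NA.
#'
#' @param path EDF file path.
#' @param age Optional patient age (years).
#' @param label Optional class label (0/1).
#' @return An [EEGRecording-class].
#' @export
readEDF <- function(path, age = NULL, label = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) readChar(con, n, useBytes = TRUE)
  rd(8)                              # version
  patientField <- trimws(rd(80))
  recField <- trimws(rd(80))
  rd(16)                             # date + time
  rd(8)                              # header bytes
  rd(44)                             # reserved
  nRecords <- as.integer(rd(8))
  recDur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))

  labels <- trimws(vapply(seq_len(ns), function(i) rd(16), ""))
  for (i in seq_len(ns)) rd(80)      # transducer
  for (i in seq_len(ns)) rd(8)       # physical dimension
  physMin <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  physMax <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  digMin <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  digMax <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  for (i in seq_len(ns)) rd(80)      # prefiltering
  spr <- as.integer(vapply(seq_len(ns), function(i) rd(8), ""))
  for (i in seq_len(ns)) rd(32)      # reserved

  if (length(unique(spr)) != 1L)
    stopf("EDF files with mixed per-signal sampling rates are not supported",
          class = "invalidInputError")
  rate <- spr[1] / recDur

  sig <- matrix(0, ns, nRecords * spr[1])
  scale <- (physMax - physMin) / (digMax - digMin)
  for (r in seq_len(nRecords)) {
    raw <- readBin(con, integer(), n = ns * spr[1], size = 2L,
                   endian = "little")
    block <- matrix(raw, nrow = spr[1], ncol = ns)
    idx <- ((r - 1L) * spr[1] + 1L):(r * spr[1])
    for (ch in seq_len(ns)) {
      sig[ch, idx] <- (block[, ch] - digMin[ch]) * scale[ch] + physMin[ch]
    }
  }

  if (is.null(age) || is.null(label)) {
    m <- regmatches(recField,
                    regexec("age=([0-9.eE+-]+|NA) label=([0-9]+|NA)",
                            recField))[[1]]
    if (length(m) == 3L) {
      if (is.null(age)) age <- suppressWarnings(as.numeric(m[2]))
      if (is.null(label)) label <- suppressWarnings(as.integer(m[3]))
    }
  }
  EEGRecording(sig, labels, rate,
               age = if (is.null(age)) NA_real_ else age,
               label = if (is.null(label)) NA_integer_ else label,
               recordingId = patientField)
}

#' Write a cohort as EDF files plus a metadata CSV
#'
#' Emits one EDF file per recording (named by recording id) and a
#' `metadata.csv` with columns `recording_id`, `file`, `age`, `label`.
#'
#' @param cohort An [EEGCohort-class].
#' @param dir Output directory (created if missing).
#' @return Path of the metadata CSV, invisibly.
#' @export
writeCohortEDF <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  n <- length(cohort)
  ids <- if (n) recordingId(cohort) else character(0)
  files <- if (n) paste0(ids, ".edf") else character(0)
  for (i in seq_len(n)) {
    writeEDF(cohort[[i]], file.path(dir, files[i]))
  }
  meta <- data.frame(
    recording_id = ids, file = files,
    age = if (n) patientAge(cohort) else numeric(0),
    label = if (n) classLabel(cohort) else integer(0)
  )
  metaPath <- file.path(dir, "metadata.csv")
  write.csv(meta, metaPath, row.names = FALSE)
  invisible(metaPath)
}

#' Read a cohort written by [writeCohortEDF()]
#'
#' @param dir Directory containing `metadata.csv` and the EDF files.
#' @return An [EEGCohort-class].
#' @export
readCohortEDF <- function(dir) {
  meta <- read.csv(file.path(dir, "metadata.csv"))
  recs <- lapply(seq_len(nrow(meta)), function(i) {
    rec <- readEDF(file.path(dir, meta$file[i]),
                   age = meta$age[i], label = meta$label[i])
    rec@recordingId <- as.character(meta$recording_id[i])
    rec@channelLabels <- normalizeChannelLabels(rec@channelLabels)
    rec
  })
  EEGCohort(recs)
}
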