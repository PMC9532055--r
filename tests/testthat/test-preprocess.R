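test_that("channel selection reorders to montage order and drops extras", {
  set.seed(1)
  labels31 <- c(standardMontage21(), paste0("X", 1:10))
  perm <- sample(31)
  rec <- EEGRecording(matrix(rnorm(31 * 100), 31, 100), labels31[perm], 250)
  sel <- selectChannels(rec)
  expect_identical(channelLabels(sel), standardMontage21())
  expect_equal(nrow(signalMatrix(sel)), 21L)
  ## the row for each electrode is the same signal regardless of input order
  expect_equal(signalMatrix(sel)["O2" == channelLabels(sel), ],
               signalMatrix(rec)[which(labels31[perm] == "O2"), ])

  ## decorated clinical labels are normalized before matching
  rec2 <- EEGRecording(matrix(rnorm(2 * 50), 2, 50),
                       c("EEG O1-REF", "EEG FP1-LE"), 250)
  sel2 <- selectChannels(rec2, c("FP1", "O1"))
  expect_identical(channelLabels(sel2), c("FP1", "O1"))

  rec3 <- EEGRecording(matrix(rnorm(20 * 10), 20, 10),
                       standardMontage21()[-21], 250)
  expect_error(selectChannels(rec3), class = "missingChannelError")
  expect_error(selectChannels(rec3), "O2")
})

test_that("resampling preserves content and scales length", {
  set.seed(2)
  rec <- EEGRecording(matrix(rnorm(500), 1, 500), "CZ", 250)
  expect_identical(resampleRecording(rec, 250), rec)  # no-op path

  rec2 <- EEGRecording(matrix(rnorm(1000), 1, 1000), "CZ", 500)
  out <- resampleRecording(rec2, 250)
  expect_equal(ncol(signalMatrix(out)), 500L)
  expect_equal(samplingRate(out), 250)

  ## 5 Hz sinusoid at 500 Hz -> 250 Hz matches the closed-form reference
  t500 <- (0:2499) / 500
  sine <- EEGRecording(matrix(sin(2 * pi * 5 * t500), 1), "CZ", 500)
  ref <- sin(2 * pi * 5 * (0:1249) / 250)
  got <- signalMatrix(resampleRecording(sine, 250))[1, ]
  expect_gt(cor(got, ref), 0.999)

  expect_error(resampleRecording(rec, -1), class = "invalidConfigError")
})

test_that("segmentation follows the strict and available policies", {
  cfg <- synthConfig(duration = 520, seed = 1L)
  rec <- generateRecording(cfg, 0, 30, seed = 42)
  seg <- segmentRecording(rec)              # strict default: 100 x 1250
  expect_equal(dim(segmentArray(seg)), c(21L, 100L, 1250L))

  ## concatenating segments reproduces the first 125,000 samples exactly
  ch <- 7L
  flat <- as.vector(t(segmentArray(seg)[ch, , ]))
  expect_identical(flat, signalMatrix(rec)[ch, 1:125000])

  short <- EEGRecording(matrix(rnorm(12 * 250), 1, 3000), "CZ", 250)
  avail <- segmentRecording(short, policy = "available")
  expect_equal(dim(segmentArray(avail))[2], 2L)   # floor(12/5)

  tooShort <- EEGRecording(matrix(rnorm(400 * 250), 1), "CZ", 250)
  expect_error(segmentRecording(tooShort), class = "insufficientDataError")
  oneWin <- EEGRecording(matrix(rnorm(6 * 250), 1), "CZ", 250)
  expect_error(segmentRecording(oneWin, policy = "available"),
               class = "insufficientDataError")
})

test_that("preprocessing is deterministic end to end", {
  rec <- smallCohort()[[1]]
  s1 <- preprocessRecording(rec, policy = "available")
  s2 <- preprocessRecording(rec, policy = "available")
  expect_identical(segmentArray(s1), segmentArray(s2))
})
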