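test_that("recording generation is deterministic and correctly shaped", {
  cfg <- synthConfig(duration = 20, seed = 5L)
  r1 <- generateRecording(cfg, label = 1, age = 40, seed = 99)
  r2 <- generateRecording(cfg, label = 1, age = 40, seed = 99)
  expect_identical(signalMatrix(r1), signalMatrix(r2))
  expect_equal(dim(signalMatrix(r1)), c(21L, 20L * 250L))
  expect_identical(channelLabels(r1), standardMontage21())

  full <- synthConfig()  # default study conditions
  expect_equal(round(full$duration * full$samplingRate), 130000)
})

test_that("pathological recordings carry more delta-band power", {
  cfg <- synthConfig(duration = 30, seed = 2L)
  norm <- generateRecording(cfg, 0, 50, seed = 123)
  path <- generateRecording(cfg, 1, 50, seed = 123)
  expect_gt(bandPower(path, c(0, 4)), bandPower(norm, c(0, 4)))
  ## independent check of the band-power oracle via spec.pgram on one channel
  pg <- function(rec) {
    s <- stats::spec.pgram(stats::ts(signalMatrix(rec)[1, ], frequency = 250),
                           plot = FALSE, taper = 0, detrend = FALSE)
    mean(s$spec[s$freq < 4])
  }
  expect_gt(pg(path), pg(norm))
})

test_that("cohort generation respects counts, determinism and age model", {
  cfg <- smallSynthConfig(seed = 3L)
  coh <- generateCohort(cfg, 3, 2)
  expect_equal(length(coh), 5L)
  expect_equal(sum(classLabel(coh)), 2L)
  coh2 <- generateCohort(cfg, 3, 2)
  expect_identical(signalMatrix(coh[[4]]), signalMatrix(coh2[[4]]))

  empty <- generateCohort(cfg, 0, 0)
  expect_equal(length(empty), 0L)

  ## ages are drawn from one shared stream; the shift flag moves only the
  ## pathological class
  cfgShift <- smallSynthConfig(seed = 3L, ageShift = 15)
  cohS <- generateCohort(cfgShift, 3, 2)
  expect_equal(patientAge(cohS)[1:3], patientAge(coh)[1:3])
  expect_equal(patientAge(cohS)[4:5], patientAge(coh)[4:5] + 15)
  expect_true(all(patientAge(coh) >= cfg$ageRange[1] &
                    patientAge(coh) <= cfg$ageRange[2]))
})

test_that("streaming featurization equals the cohort-at-once path", {
  cfg <- smallSynthConfig(seed = 11L)
  streamed <- synthesizeFeatureTensors(cfg, 2, 2, policy = "available")
  batch <- featurizeCohort(generateCohort(cfg, 2, 2), policy = "available")
  expect_equal(length(streamed), length(batch))
  for (i in seq_along(streamed)) {
    expect_identical(featureValues(streamed[[i]]),
                     featureValues(batch[[i]]))
    expect_identical(patientAge(streamed[[i]]), patientAge(batch[[i]]))
  }
})

test_that("invalid generator configurations are rejected", {
  expect_error(synthConfig(duration = -5), class = "invalidConfigError")
  expect_error(synthConfig(abnormalDeltaGain = 0),
               class = "invalidConfigError")
  expect_error(synthConfig(nChannels = 4),
               class = "invalidConfigError")
  expect_error(generateRecording(smallSynthConfig(), label = 2, age = 1,
                                 seed = 1),
               class = "invalidConfigError")
})
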