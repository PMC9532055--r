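## Independent direct-summation oracle for the six statistics (population
## conventions, excess kurtosis), written as explicit loops.
oracleStats <- function(x) {
  m <- length(x)
  u <- 0; for (v in x) u <- u + v; u <- u / m
  mad <- 0; s2 <- 0; s3 <- 0; s4 <- 0; mav <- 0
  for (v in x) {
    d <- v - u
    mad <- mad + abs(d); s2 <- s2 + d^2; s3 <- s3 + d^3; s4 <- s4 + d^4
    mav <- mav + abs(v)
  }
  mad <- mad / m; s2 <- s2 / m; s3 <- s3 / m; s4 <- s4 / m; mav <- mav / m
  c(mv = u, mad = mad, sd = sqrt(s2), mav = mav,
    skew = if (s2 > 0) s3 / s2^1.5 else 0,
    kurt = if (s2 > 0) s4 / s2^2 - 3 else 0)
}

test_that("statistics match hand-worked and oracle values", {
  s <- computeStatistics(c(1, 2, 3))
  expect_equal(s[["mv"]], 2)
  expect_equal(s[["mad"]], 2 / 3)
  expect_equal(s[["sd"]], sqrt(2 / 3))   # population convention
  expect_equal(s[["mav"]], 2)
  expect_equal(s[["skew"]], 0)

  const <- computeStatistics(rep(5, 4))
  expect_equal(unname(const), c(5, 0, 0, 5, 0, 0))  # zero-variance guard

  ## 100 seeded sequences against the direct-summation oracle
  for (i in 1:100) {
    x <- lcgSequence(if (i %% 7 == 0) 1250L else 50L + i, seed = i) * 10 - 5
    expect_equal(computeStatistics(x), oracleStats(x), tolerance = 1e-10)
  }
  expect_error(computeStatistics(numeric(0)), class = "invalidInputError")
})

test_that("skewness and kurtosis agree with e1071 moment estimators", {
  skip_if_not_installed("e1071")
  x <- lcgSequence(1250, seed = 77) ^ 2
  s <- computeStatistics(x)
  expect_equal(s[["skew"]], e1071::skewness(x, type = 1), tolerance = 1e-12)
  expect_equal(s[["kurt"]], e1071::kurtosis(x, type = 1), tolerance = 1e-12)
})

test_that("z-normalization yields zero mean and unit population SD", {
  expect_equal(normalizeVector(c(2, 4)), c(-1, 1))
  expect_equal(normalizeVector(rep(3, 5)), rep(0, 5))  # guard
  v <- lcgSequence(24, seed = 4) * 100
  z <- normalizeVector(v)
  expect_equal(mean(z), 0, tolerance = 1e-10)
  expect_equal(sqrt(mean((z - mean(z))^2)), 1, tolerance = 1e-10)
  expect_error(normalizeVector(1), class = "invalidInputError")
})

test_that("segment featurization has the documented layout", {
  x <- lcgSequence(1250, seed = 9) - 0.5
  v <- featurizeSegment(x)
  expect_length(v, 24L)
  expect_identical(names(v)[1:6],
                   c("mv_A5", "mad_A5", "sd_A5", "mav_A5", "skew_A5",
                     "kurt_A5"))
  expect_identical(names(v)[19:24],
                   c("mv_D3", "mad_D3", "sd_D3", "mav_D3", "skew_D3",
                     "kurt_D3"))
  expect_identical(v, featurizeSegment(x))  # deterministic

  z <- featurizeSegment(numeric(1250), normalize = FALSE)
  expect_true(all(z == 0))  # zero in, zero features (guards included)

  ## scale covariance of the raw statistics under k > 0: the amplitude
  ## statistics scale with k, the shape statistics are invariant
  raw1 <- featurizeSegment(x, normalize = FALSE)
  raw2 <- featurizeSegment(2 * x, normalize = FALSE)
  scaleIdx <- grep("^(mv|mad|sd|mav)_", names(raw1))
  expect_equal(raw2[scaleIdx], 2 * raw1[scaleIdx], tolerance = 1e-10)
  shapeIdx <- grep("^(skew|kurt)_", names(raw1))
  expect_equal(raw2[shapeIdx], raw1[shapeIdx], tolerance = 1e-10)
})

test_that("recording featurization matches the per-segment path", {
  seg <- preprocessRecording(smallCohort()[[2]], policy = "available")
  ft <- featurizeRecording(seg)
  d <- dim(featureValues(ft))
  expect_equal(d[1], 21L)
  expect_equal(d[3], 24L)
  ## vectorized tensor equals the scalar path for a spot-checked window
  direct <- featurizeSegment(segmentArray(seg)[13, 3, ])
  expect_equal(featureValues(ft)[13, 3, ], unname(direct),
               tolerance = 1e-12)
  expect_equal(patientAge(ft), patientAge(seg))
  expect_equal(classLabel(ft), classLabel(seg))
})

test_that("cohort-wide per-feature scaling standardizes each feature", {
  tensors <- featurizeCohort(
    EEGCohort(list(smallCohort()[[1]], smallCohort()[[7]])),
    policy = "available", normalizationScope = "per_feature")
  pooled <- do.call(rbind, lapply(tensors, function(tt) {
    matrix(featureValues(tt), ncol = 24)
  }))
  expect_equal(max(abs(colMeans(pooled))), 0, tolerance = 1e-8)
  sds <- sqrt(colMeans(pooled^2) - colMeans(pooled)^2)
  expect_equal(unname(sds), rep(1, 24), tolerance = 1e-8)
})
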