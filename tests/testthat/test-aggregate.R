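## Build a FeatureTensor directly from an array, for layout arithmetic.
toyTensor <- function(values, age = 33, label = 1L) {
  d <- dim(values)
  new("FeatureTensor", values = values,
      featureNames = sprintf("f%02d", seq_len(d[3])),
      channelLabels = paste0("CH", seq_len(d[1])),
      age = age, label = as.integer(label), recordingId = "toy")
}

test_that("aggregation computes front/rear/global SDs with hand values", {
  ## one channel, one feature, series [1,1,3,3]
  vals <- array(c(1, 1, 3, 3), dim = c(1, 4, 1))
  v <- aggregateFeatures(toyTensor(vals), aggregationConfig())
  expect_equal(unname(v),
               c(0, 0, 1, 33))  # front SD, rear SD, global (population) SD, age
  expect_named(v, c("CH1_front_f01", "CH1_rear_f01", "CH1_global_f01",
                    "age"))

  constant <- toyTensor(array(7, dim = c(2, 6, 3)))
  vc <- aggregateFeatures(toyTensor(array(7, c(2, 6, 3))),
                          aggregationConfig(includeAge = FALSE))
  expect_true(all(vc == 0))
})

test_that("dimension law holds over randomized shapes", {
  set.seed(42)
  for (i in 1:10) {
    C <- sample(1:8, 1); S <- sample(2:12, 1); FF <- sample(1:30, 1)
    tt <- toyTensor(array(rnorm(C * S * FF), c(C, S, FF)))
    expect_length(aggregateFeatures(tt), C * 3 * FF + 1)
    expect_length(aggregateFeatures(tt, aggregationConfig("global")),
                  C * FF + 1)
    expect_length(
      aggregateFeatures(tt, aggregationConfig(c("front", "rear"),
                                              includeAge = FALSE)),
      C * 2 * FF)
  }
})

test_that("aggregation is permutation-invariant within halves", {
  set.seed(7)
  C <- 3L; S <- 10L; FF <- 5L
  arr <- array(rnorm(C * S * FF), c(C, S, FF))
  v0 <- aggregateFeatures(toyTensor(arr))
  half <- S / 2
  shuffled <- arr[, c(sample(1:half), sample((half + 1):S)), ]
  expect_equal(aggregateFeatures(toyTensor(shuffled)), v0,
               tolerance = 1e-12)
  ## non-age entries are SDs, hence non-negative
  expect_true(all(v0[names(v0) != "age"] >= 0))
  ## identical halves => front equals rear
  arrSym <- arr; arrSym[, (half + 1):S, ] <- arr[, 1:half, ]
  vs <- aggregateFeatures(toyTensor(arrSym))
  expect_equal(vs[grep("_front_", names(vs))],
               vs[grep("_rear_", names(vs))], ignore_attr = TRUE)
})

test_that("odd segment counts put the extra segment in the front half", {
  vals <- array(c(1, 1, 1, 5, 5), dim = c(1, 5, 1))  # front = 1,1,1
  v <- aggregateFeatures(toyTensor(vals), aggregationConfig(
    c("front", "rear"), includeAge = FALSE))
  expect_equal(unname(v), c(0, 0))
  expect_error(
    aggregateFeatures(toyTensor(array(1, c(1, 1, 1)))),
    class = "insufficientSegmentsError")
})

test_that("feature variants have the documented lengths", {
  tt <- smallTensors()[[1]]
  d <- dim(featureValues(tt))        # 21 x 7 x 24
  expect_length(buildFeatureVariant(tt, 1), prod(d) + 1)
  expect_length(buildFeatureVariant(tt, 2), d[1] * d[3] + 1)
  expect_length(buildFeatureVariant(tt, 3), d[1] * 2 * d[3] + 1)
  expect_identical(buildFeatureVariant(tt, 4),
                   aggregateFeatures(tt, aggregationConfig()))
  expect_error(buildFeatureVariant(tt, 5), class = "invalidConfigError")
  ## case-1 flatten preserves values in channel-major order
  v1 <- buildFeatureVariant(tt, 1, includeAge = FALSE)
  expect_equal(unname(v1[1:24]), featureValues(tt)[1, 1, ])
  expect_equal(unname(v1[25:48]), featureValues(tt)[1, 2, ])
})

test_that("design matrix round-trips through CSV", {
  se <- designMatrix(smallTensors()[1:4])
  expect_equal(dim(SummarizedExperiment::assay(se)), c(1513L, 4L))
  expect_identical(SummarizedExperiment::colData(se)$label,
                   classLabel(smallCohort())[1:4])
  path <- withr::local_tempfile(fileext = ".csv")
  writeDesignMatrix(se, path)
  back <- readDesignMatrix(path)
  expect_equal(unname(back$x),
               unname(t(SummarizedExperiment::assay(se))),
               tolerance = 1e-12)
  expect_identical(back$label, classLabel(smallCohort())[1:4])
  expect_identical(colnames(back$x),
                   rownames(SummarizedExperiment::assay(se)))
})
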