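test_that("confusion counts follow the pathological-positive convention", {
  cc <- confusionCounts(c(1, 1, 0, 0), c(1, 0, 0, 1))
  expect_equal(cc, c(TP = 1L, TN = 1L, FP = 1L, FN = 1L))
  perfect <- confusionCounts(c(1, 0, 1), c(1, 0, 1))
  expect_equal(perfect[["FP"]] + perfect[["FN"]], 0L)
  allMissed <- confusionCounts(rep(1, 5), rep(0, 5))
  expect_equal(allMissed[["TP"]], 0L)
  expect_equal(allMissed[["FN"]], 5L)
  expect_error(confusionCounts(c(1, 0), 1), class = "invalidInputError")
  expect_error(confusionCounts(c(2, 0), c(1, 0)),
               class = "invalidInputError")
})

test_that("metric formulas reproduce hand-worked values and guards", {
  m <- metricsFromConfusion(c(TP = 1, TN = 1, FP = 0, FN = 0))
  expect_equal(unname(m), rep(1, 4))

  m2 <- metricsFromConfusion(c(TP = 3, TN = 2, FP = 1, FN = 4))
  expect_equal(m2[["accuracy"]], 5 / 10)
  expect_equal(m2[["sensitivity"]], 3 / 7)
  expect_equal(m2[["specificity"]], 2 / 3)
  expect_equal(m2[["f1"]], 6 / 11)

  ## accuracy is the prevalence-weighted mean of sensitivity/specificity
  n <- 10
  wPos <- (3 + 4) / n; wNeg <- (2 + 1) / n
  expect_equal(m2[["accuracy"]],
               wPos * m2[["sensitivity"]] + wNeg * m2[["specificity"]])

  w <- capture_warnings(
    und <- metricsFromConfusion(c(TP = 0, TN = 3, FP = 0, FN = 0)))
  expect_match(w, "sensitivity", all = FALSE)
  expect_match(w, "f1", all = FALSE)
  expect_true(is.na(und[["sensitivity"]]))
  expect_true(is.na(und[["f1"]]))
  expect_equal(und[["specificity"]], 1)
})

test_that("cross-validation partitions correctly and is reproducible", {
  td <- local({
    set.seed(9)
    x <- matrix(rnorm(100 * 6), 100, 6,
                dimnames = list(NULL, paste0("f", 1:6)))
    y <- rep(0:1, each = 50)
    x[, 2] <- x[, 2] + 3 * y
    list(x = x, y = as.integer(y))
  })
  res <- crossValidate(td$x, td$y, fastSpec(), k = 10, seed = 4)
  expect_equal(sum(res$pooled), 100)
  expect_equal(sum(res$perFold$TP + res$perFold$TN + res$perFold$FP +
                     res$perFold$FN), 100)
  expect_equal(unname(res$pooled),
               unname(colSums(res$perFold[, c("TP", "TN", "FP", "FN")])),
               ignore_attr = TRUE)
  ## every recording validated exactly once, folds near-equal, stratified
  expect_equal(unname(table(res$foldAssignment)), rep(10L, 10),
               ignore_attr = TRUE)
  expect_equal(res$mean,
               colMeans(res$perFold[, c("accuracy", "sensitivity",
                                        "specificity", "f1")]))
  expect_gt(res$mean[["accuracy"]], 0.5)

  res2 <- crossValidate(td$x, td$y, fastSpec(), k = 10, seed = 4)
  expect_identical(res$foldAssignment, res2$foldAssignment)
  expect_identical(res$perFold, res2$perFold)

  expect_error(crossValidate(td$x[1:5, ], td$y[1:5], fastSpec(), k = 10),
               class = "invalidConfigError")
})

test_that("region subsetting preserves montage order and shrinks layouts", {
  tt <- smallTensors()[[1]]
  all6 <- regionSubset(tt, names(regionMap()))
  expect_identical(channelLabels(all6), standardMontage21())

  noFrontal <- regionSubset(tt, setdiff(names(regionMap()), "frontal"))
  expect_equal(length(channelLabels(noFrontal)), 14L)
  expect_length(aggregateFeatures(noFrontal), 14 * 3 * 24 + 1)

  ear <- regionSubset(tt, "ear")
  expect_identical(channelLabels(ear), c("A1", "A2"))

  expect_error(regionSubset(tt, "cerebellum"), class = "invalidConfigError")
  expect_error(regionSubset(tt, character(0)), class = "invalidConfigError")

  ## the six regions partition the montage
  expect_setequal(unlist(regionMap()), standardMontage21())
  expect_equal(sum(lengths(regionMap())), 21L)
})

test_that("ablation protocols emit one row per condition", {
  tensors <- smallTensors()
  trainT <- tensors[c(1:4, 7:10)]
  testT <- tensors[c(5, 6, 11, 12)]
  spec <- fastSpec()

  cases <- runAblation(trainT, testT, spec, "cases")
  expect_equal(nrow(cases), 4L)
  expect_identical(cases$condition, paste0("case", 1:4))
  expect_equal(cases$nFeatures[4], 21 * 3 * 24 + 1)
  expect_equal(cases$nFeatures[2], 21 * 24 + 1)

  age <- runAblation(trainT, testT, spec, "age")
  expect_equal(nrow(age), 2L)
  expect_equal(age$nFeatures, c(1513, 1512))

  regions <- runAblation(trainT, testT, spec, "regions")
  expect_equal(nrow(regions), 7L)
  expect_identical(regions$condition[1], "all")
  expect_true(all(regions$TP + regions$TN + regions$FP + regions$FN == 4))
})
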