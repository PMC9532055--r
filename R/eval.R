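#' Confusion counts with pathological as the positive class
#'
#' TP counts recordings correctly identified as pathological, TN those
#' correctly identified as normal, FP normals misclassified as
#' pathological and FN pathologicals missed.
#'
#' @param truth Integer vector of true labels (0/1).
#' @param predicted Integer vector of predicted labels (0/1).
#' @return Named integer vector `c(TP, TN, FP, FN)`.
#' @examples
#' confusionCounts(c(1, 1, 0, 0), c(1, 0, 0, 1))
#' @export
confusionCounts <- function(truth, predicted) {
  if (length(truth) != length(predicted))
    stopf("truth and predicted have different lengths (%d vs %d)",
          length(truth), length(predicted), class = "invalidInputError")
  if (!all(truth %in% c(0, 1)) || !all(predicted %in% c(0, 1)))
    stopf("labels must be 0 or 1", class = "invalidInputError")
  c(TP = sum(truth == 1 & predicted == 1),
    TN = sum(truth == 0 & predicted == 0),
    FP = sum(truth == 0 & predicted == 1),
    FN = sum(truth == 1 & predicted == 0))
}

#' Metrics from confusion counts
#'
#' Accuracy = (TP+TN)/(TP+FP+TN+FN), sensitivity = TP/(TP+FN),
#' specificity = TN/(TN+FP), F1 = 2 TP/(2 TP + FP + FN).  A metric whose
#' denominator is zero is returned as NA with a warning rather than a
#' silent 0.
#'
#' @param counts Named vector from [confusionCounts()], or TP when the
#'   four counts are given separately.
#' @param TN,FP,FN Remaining counts when given separately.
#' @param percent Return percentages rounded to 2 decimal places
#'   (half-even) instead of fractions.
#' @return Named numeric vector
#'   `c(accuracy, sensitivity, specificity, f1)`.
#' @examples
#' metricsFromConfusion(c(TP = 107, TN = 139, FP = 11, FN = 19),
#'                      percent = TRUE)
#' @export
metricsFromConfusion <- function(counts, TN = NULL, FP = NULL, FN = NULL,
                                 percent = FALSE) {
  if (!is.null(TN)) {
    counts <- c(TP = counts, TN = TN, FP = FP, FN = FN)
  }
  tp <- counts[["TP"]]; tn <- counts[["TN"]]
  fp <- counts[["FP"]]; fn <- counts[["FN"]]
  if (any(c(tp, tn, fp, fn) < 0))
    stopf("confusion counts must be non-negative",
          class = "invalidInputError")
  safeDiv <- function(num, den, what) {
    if (den == 0) {
      warning(sprintf("%s undefined: zero denominator", what))
      return(NA_real_)
    }
    num / den
  }
  m <- c(
    accuracy = safeDiv(tp + tn, tp + fp + tn + fn, "accuracy"),
    sensitivity = safeDiv(tp, tp + fn, "sensitivity"),
    specificity = safeDiv(tn, tn + fp, "specificity"),
    f1 = safeDiv(2 * tp, 2 * tp + fp + fn, "f1")
  )
  if (percent) round(100 * m, 2) else m
}

#' Stratified k-fold cross-validation
#'
#' Randomly partitions the recordings into k near-equal folds (stratified
#' by class, seeded), trains on k-1 folds and validates on the held-out
#' fold, repeating until every recording has been validated exactly once.
#'
#' @param x Recordings x features matrix (or [designMatrix()] result).
#' @param labels Integer class labels.
#' @param spec A [modelSpec()].
#' @param k Number of folds (default 10).
#' @param seed Partition seed.
#' @return List with `pooled` ([confusionCounts()] summed over folds),
#'   `perFold` (data frame of per-fold metrics), `mean` (mean of the
#'   per-fold metrics) and `foldAssignment`.
#' @export
crossValidate <- function(x, labels = NULL, spec = modelSpec(), k = 10L,
                          seed = 1L) {
  if (is(x, "SummarizedExperiment") && is.null(labels))
    labels <- colData(x)$label
  x <- asRowMatrix(x)
  labels <- as.integer(labels)
  n <- nrow(x)
  if (k > n)
    stopf("k (%d) exceeds number of recordings (%d)", k, n,
          class = "invalidConfigError")
  set.seed(as.integer(seed))
  fold <- integer(n)
  for (cl in unique(labels)) {
    idx <- sample(which(labels == cl))
    fold[idx] <- rep(seq_len(k), length.out = length(idx))
  }
  perFold <- vector("list", k)
  pooled <- c(TP = 0L, TN = 0L, FP = 0L, FN = 0L)
  for (f in seq_len(k)) {
    testIdx <- which(fold == f)
    trainIdx <- which(fold != f)
    model <- trainModel(x[trainIdx, , drop = FALSE], labels[trainIdx], spec)
    pred <- predict(model, x[testIdx, , drop = FALSE])
    cc <- confusionCounts(labels[testIdx], pred)
    pooled <- pooled + cc
    perFold[[f]] <- c(fold = f, cc, metricsFromConfusion(cc))
  }
  perFold <- as.data.frame(do.call(rbind, perFold))
  meanMetrics <- colMeans(perFold[, c("accuracy", "sensitivity",
                                      "specificity", "f1")])
  list(pooled = pooled, perFold = perFold, mean = meanMetrics,
       foldAssignment = fold)
}

#' Restrict a feature tensor to brain regions
#'
#' Keeps only the channels belonging to the included regions, preserving
#' montage order.  Downstream aggregated vectors shrink accordingly
#' (`C' * 3 * F + 1`).
#'
#' @param tensor A [FeatureTensor-class].
#' @param includeRegions Region names, a subset of `names(map)`.
#' @param map Region-to-electrode map; default [regionMap()].
#' @return A [FeatureTensor-class] with the reduced channel set.
#' @export
regionSubset <- function(tensor, includeRegions, map = regionMap()) {
  stopifnot(is(tensor, "FeatureTensor"))
  unknown <- setdiff(includeRegions, names(map))
  if (length(unknown))
    stopf("unknown region(s): %s", paste(unknown, collapse = ", "),
          class = "invalidConfigError")
  if (!length(includeRegions))
    stopf("at least one region required", class = "invalidConfigError")
  keep <- unlist(map[includeRegions], use.names = FALSE)
  idx <- which(tensor@channelLabels %in% keep)
  if (!length(idx))
    stopf("selected regions cover none of the tensor's channels",
          class = "invalidConfigError")
  new("FeatureTensor", values = tensor@values[idx, , , drop = FALSE],
      featureNames = tensor@featureNames,
      channelLabels = tensor@channelLabels[idx],
      age = tensor@age, label = tensor@label,
      recordingId = tensor@recordingId)
}

#' @noRd
evalCondition <- function(trainTensors, testTensors, spec, case = 4L,
                          includeAge = TRUE, regions = NULL) {
  if (!is.null(regions)) {
    trainTensors <- lapply(trainTensors, regionSubset, includeRegions = regions)
    testTensors <- lapply(testTensors, regionSubset, includeRegions = regions)
  }
  seTrain <- designMatrix(trainTensors, case = case, includeAge = includeAge)
  seTest <- designMatrix(testTensors, case = case, includeAge = includeAge)
  model <- trainModel(seTrain, spec = spec)
  te <- designRows(seTest)
  cc <- confusionCounts(te$label, predict(model, te$x))
  c(cc, metricsFromConfusion(cc), nFeatures = nrow(assay(seTrain)))
}

#' Ablation protocols
#'
#' Runs one of the three ablation experiments on a fixed train/test split,
#' returning one metrics row per condition:
#' \describe{
#'   \item{`"cases"`}{the four aggregation variants of
#'     [buildFeatureVariant()] (raw flatten; global only; local only;
#'     full multi-scale), all with age.}
#'   \item{`"age"`}{the full aggregation with and without the appended
#'     age.}
#'   \item{`"regions"`}{all six brain regions, then each
#'     leave-one-region-out combination (7 conditions).}
#' }
#'
#' @param trainTensors,testTensors Lists of [FeatureTensor-class] objects
#'   carrying class labels.
#' @param spec A [modelSpec()] used for every condition.
#' @param protocol `"cases"`, `"age"` or `"regions"`.
#' @return Data frame with one row per condition: confusion counts, the
#'   four metrics and the feature-space size.
#' @export
runAblation <- function(trainTensors, testTensors, spec = modelSpec(),
                        protocol = c("cases", "age", "regions")) {
  protocol <- match.arg(protocol)
  rows <- switch(protocol,
    cases = {
      res <- lapply(1:4, function(cs)
        evalCondition(trainTensors, testTensors, spec, case = cs))
      names(res) <- paste0("case", 1:4)
      res
    },
    age = {
      list(with_age = evalCondition(trainTensors, testTensors, spec,
                                    includeAge = TRUE),
           without_age = evalCondition(trainTensors, testTensors, spec,
                                       includeAge = FALSE))
    },
    regions = {
      regs <- names(regionMap())
      combos <- c(list(all = regs),
                  stats::setNames(lapply(regs, function(r) setdiff(regs, r)),
                                  paste0("minus_", regs)))
      lapply(combos, function(rr)
        evalCondition(trainTensors, testTensors, spec, regions = rr))
    })
  out <- as.data.frame(do.call(rbind, rows))
  out$condition <- names(rows)
  out[, c("condition", setdiff(colnames(out), "condition"))]
}
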