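#' Pipeline configuration
#'
#' One nested configuration object covering every stage, with defaults
#' reproducing the standard protocol (21-electrode montage, 250 Hz,
#' 100 five-second segments, sym6 level-5 decomposition with A5/D5/D4/D3,
#' per-vector z-scoring, three-scale aggregation with age, the 680-tree
#' depth-4 booster, 10-fold CV).  Round-trips losslessly through YAML;
#' unknown keys are rejected.
#'
#' @param ... Named overrides of the form `section$key`, given as nested
#'   lists, e.g. `pipelineConfig(synth = list(duration = 60))`.
#' @return A `PipelineConfig` list.
#' @export
pipelineConfig <- function(...) {
  defaults <- list(
    synth = list(nNormal = 60L, nAbnormal = 60L, duration = 520,
                 samplingRate = 250, abnormalDeltaGain = 3, burstRate = 6,
                 ageMin = 1, ageMax = 90, ageShift = 0, seed = 1L),
    preprocess = list(montage = standardMontage21(), targetRate = 250,
                      windowSeconds = 5, nSegments = 100L,
                      policy = "strict"),
    features = list(waveletName = "sym6", levels = 5L,
                    selectedSubbands = c("A5", "D5", "D4", "D3"),
                    extensionMode = "symmetric",
                    sdConvention = "population",
                    normalizationScope = "per_vector"),
    aggregate = list(scales = c("front", "rear", "global"),
                     includeAge = TRUE, case = 4L),
    model = list(backend = "gbdt", nTrees = 680L, maxDepth = 4L,
                 learningRate = 0.0343, seed = 1L),
    eval = list(k = 10L, seed = 1L)
  )
  overrides <- list(...)
  unknownSections <- setdiff(names(overrides), names(defaults))
  if (length(unknownSections))
    stopf("unknown config section(s): %s",
          paste(unknownSections, collapse = ", "),
          class = "invalidConfigError")
  for (sec in names(overrides)) {
    unknownKeys <- setdiff(names(overrides[[sec]]), names(defaults[[sec]]))
    if (length(unknownKeys))
      stopf("unknown key(s) in section '%s': %s", sec,
            paste(unknownKeys, collapse = ", "),
            class = "invalidConfigError")
    defaults[[sec]][names(overrides[[sec]])] <- overrides[[sec]]
  }
  structure(defaults, class = "PipelineConfig")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file path.
#' @return A [pipelineConfig()], validated against the known keys.
#' @export
readPipelineConfig <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipelineConfig, raw)
}

#' Write a pipeline configuration to YAML
#'
#' @param config A [pipelineConfig()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
writePipelineConfig <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @noRd
synthConfigFrom <- function(config) {
  synthConfig(duration = config$synth$duration,
              samplingRate = config$synth$samplingRate,
              abnormalDeltaGain = config$synth$abnormalDeltaGain,
              burstRate = config$synth$burstRate,
              ageRange = c(config$synth$ageMin, config$synth$ageMax),
              ageShift = config$synth$ageShift,
              seed = config$synth$seed)
}

#' @noRd
waveletConfigFrom <- function(config) {
  waveletConfig(waveletName = config$features$waveletName,
                levels = config$features$levels,
                selectedSubbands = config$features$selectedSubbands,
                extensionMode = config$features$extensionMode,
                sdConvention = config$features$sdConvention)
}

#' Simulate a cohort and write it to disk
#'
#' Generates the configured synthetic cohort and writes one EDF file per
#' recording plus `metadata.csv` (see [writeCohortEDF()]).
#'
#' @param config A [pipelineConfig()].
#' @param outDir Output directory.
#' @return Path of the metadata CSV, invisibly.
#' @export
cmdSimulate <- function(config, outDir) {
  stopifnot(inherits(config, "PipelineConfig"))
  cohort <- generateCohort(synthConfigFrom(config),
                           config$synth$nNormal, config$synth$nAbnormal)
  writeCohortEDF(cohort, outDir)
}

#' Featurize a cohort directory into a design-matrix CSV
#'
#' Reads the EDF cohort written by [cmdSimulate()] (or any directory in
#' the same layout), runs preprocessing, wavelet feature extraction and
#' multi-scale aggregation, and writes the per-recording design matrix.
#'
#' @param config A [pipelineConfig()].
#' @param cohortDir Directory with `metadata.csv` and EDF files.
#' @param out Output CSV path.
#' @return `out`, invisibly.
#' @export
cmdFeaturize <- function(config, cohortDir, out) {
  stopifnot(inherits(config, "PipelineConfig"))
  cohort <- readCohortEDF(cohortDir)
  tensors <- featurizeCohort(
    cohort, montage = config$preprocess$montage,
    targetRate = config$preprocess$targetRate,
    windowSeconds = config$preprocess$windowSeconds,
    nSegments = config$preprocess$nSegments,
    policy = config$preprocess$policy,
    config = waveletConfigFrom(config),
    normalizationScope = config$features$normalizationScope)
  se <- designMatrix(tensors, case = config$aggregate$case,
                     includeAge = config$aggregate$includeAge)
  writeDesignMatrix(se, out)
}

#' Train and evaluate from design-matrix CSVs
#'
#' Trains the configured classifier on `trainCsv`.  With `testCsv`, the
#' four metrics and the confusion matrix on the held-out rows are
#' reported; with `cv = TRUE`, stratified k-fold cross-validation on
#' `trainCsv` is reported instead.  Writes `metrics.csv` and
#' `model.bundle` under `outDir`.
#'
#' @param config A [pipelineConfig()].
#' @param trainCsv Training design-matrix CSV ([writeDesignMatrix()]).
#' @param testCsv Optional held-out design-matrix CSV.
#' @param outDir Output directory.
#' @param cv Run cross-validation instead of a held-out evaluation.
#' @return The metrics data frame, invisibly.
#' @export
cmdTrainEval <- function(config, trainCsv, testCsv = NULL, outDir,
                         cv = FALSE) {
  stopifnot(inherits(config, "PipelineConfig"))
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  tr <- readDesignMatrix(trainCsv)
  spec <- modelSpec(config$model$backend, config$model$nTrees,
                    config$model$maxDepth, config$model$learningRate,
                    seed = config$model$seed)
  if (cv) {
    res <- crossValidate(tr$x, tr$label, spec, k = config$eval$k,
                         seed = config$eval$seed)
    metrics <- rbind(
      data.frame(scope = "pooled",
                 t(c(res$pooled, metricsFromConfusion(res$pooled)))),
      data.frame(scope = "mean_over_folds", TP = NA, TN = NA, FP = NA,
                 FN = NA, t(res$mean)))
  } else {
    model <- trainModel(tr$x, tr$label, spec)
    saveEEGModel(model, file.path(outDir, "model.bundle"))
    ev <- if (is.null(testCsv)) tr else readDesignMatrix(testCsv)
    cc <- confusionCounts(ev$label, predict(model, ev$x))
    metrics <- data.frame(
      scope = if (is.null(testCsv)) "training_set" else "test_set",
      t(c(cc, metricsFromConfusion(cc))))
  }
  write.csv(metrics, file.path(outDir, "metrics.csv"), row.names = FALSE)
  invisible(metrics)
}

#' Run an ablation protocol from two cohort directories
#'
#' @param config A [pipelineConfig()].
#' @param trainDir,testDir Cohort directories ([cmdSimulate()] layout).
#' @param protocol `"cases"`, `"age"` or `"regions"`.
#' @param out Output CSV path for the results table.
#' @return The results data frame, invisibly.
#' @export
cmdAblate <- function(config, trainDir, testDir, protocol, out) {
  stopifnot(inherits(config, "PipelineConfig"))
  featurize <- function(dir) {
    featurizeCohort(
      readCohortEDF(dir), montage = config$preprocess$montage,
      targetRate = config$preprocess$targetRate,
      windowSeconds = config$preprocess$windowSeconds,
      nSegments = config$preprocess$nSegments,
      policy = config$preprocess$policy,
      config = waveletConfigFrom(config),
      normalizationScope = config$features$normalizationScope)
  }
  spec <- modelSpec(config$model$backend, config$model$nTrees,
                    config$model$maxDepth, config$model$learningRate,
                    seed = config$model$seed)
  res <- runAblation(featurize(trainDir), featurize(testDir), spec,
                     protocol)
  write.csv(res, out, row.names = FALSE)
  invisible(res)
}
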