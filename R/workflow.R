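#' @title End-to-end pipeline
#' @name workflow
#' @description Orchestrates phantom generation, tooth detection, exam-level
#' splitting, class-balancing augmentation, classifier training, metric
#' evaluation and the per-exam agreement analysis from a single nested
#' configuration with one global seed. Every stage seed is derived from the
#' global seed, so a run is fully reproducible from its configuration.
NULL

#' Default pipeline configuration
#'
#' Returns the nested configuration list consumed by
#' \code{\link{runPipeline}}. Any entry can be overridden via \code{...}
#' (top-level) or by editing the returned list; \code{\link{readPipelineConfig}}
#' merges a YAML file over these defaults.
#'
#' Defaults: 40 phantom exams of 6--8 teeth at 800 x 600 (enough exams that
#' an exam-disjoint test set of 15 teeth per class exists at realistic
#' lesion prevalence), detection at the default parameters, 4/12/24
#' augmentation, and a \code{tiny} classifier trained for 500 steps at
#' learning rate 0.001.
#'
#' @param ... top-level overrides, e.g. \code{nExams = 8}.
#' @return Named list of pipeline settings.
#' @export
#' @examples
#' cfg <- pipelineConfig(nExams = 6)
pipelineConfig <- function(...) {
  cfg <- list(
    seed = 1L,
    nExams = 40L,
    teethPerRow = c(3L, 4L),       # cycled across exams: 6-8 teeth/image
    phantom = list(width = 800, height = 600, rows = 2),
    detection = list(),
    matchIoU = 0.3,
    split = list(testPerClass = 15L),
    augment = list(),
    train = list(architecture = "tiny", learningRate = 0.001,
                 iterations = 500L, inputSize = 64),
    outDir = NULL)
  over <- list(...)
  mergeConfig(cfg, over)
}

mergeConfig <- function(base, over) {
  for (nm in names(over)) {
    if (is.list(base[[nm]]) && is.list(over[[nm]]))
      base[[nm]] <- mergeConfig(base[[nm]], over[[nm]])
    else base[[nm]] <- over[[nm]]
  }
  base
}

#' Read a pipeline configuration from YAML
#'
#' Keys present in the file override the defaults of
#' \code{\link{pipelineConfig}}; all others keep their default values.
#'
#' @param path YAML file path.
#' @return Named configuration list.
#' @export
readPipelineConfig <- function(path) {
  mergeConfig(pipelineConfig(), yaml::read_yaml(path))
}

# Exam-disjoint split: accumulate shuffled exams into the test pool until
# every class has testPerClass candidates, then draw exactly testPerClass
# test crops per class from that pool. Crops of test exams that are not
# drawn are discarded (never trained on), keeping train/test exam ids
# disjoint.
splitByExam <- function(crops, testPerClass, seed) {
  labs <- cropLabels(crops)
  exams <- cropExams(crops)
  withSeed(seed, {
    ord <- sample(unique(exams))
    cum <- stats::setNames(rep(0L, 3), cariesStages())
    testExams <- character()
    for (e in ord) {
      if (all(cum >= testPerClass)) break
      testExams <- c(testExams, e)
      tab <- table(labs[exams == e])
      cum[names(tab)] <- cum[names(tab)] + as.integer(tab)
    }
    if (!all(cum >= testPerClass))
      stop("split error: not enough teeth per class for an exam-disjoint ",
           "test set; increase nExams", call. = FALSE)
    inPool <- which(exams %in% testExams)
    testIdx <- unlist(lapply(cariesStages(), function(cls)
      sort(sample(inPool[labs[inPool] == cls], testPerClass))))
    list(train = crops[setdiff(seq_along(labs), inPool)],
         test = crops[sort(testIdx)], testExams = testExams)
  })
}

stageMsg <- function(verbose, ...) if (verbose) message(sprintf(...))

#' Run the full pipeline
#'
#' Executes phantom generation, detection, split, augmentation, training,
#' evaluation and the per-exam agreement analysis. With an output
#' directory, writes all intermediate artifacts (phantom images and masks,
#' ground truth, crops, label table, training log, model, evaluation
#' report).
#'
#' @param config configuration list from \code{\link{pipelineConfig}} or
#'   \code{\link{readPipelineConfig}}.
#' @param outDir output directory (overrides \code{config$outDir};
#'   \code{NULL} writes nothing).
#' @param verbose log stage progress?
#' @return A run-report list: dataset and detection summaries, the
#'   confusion matrix, metric table, AUCs, per-exam agreement tests, and
#'   the minimum-sample-size check.
#' @export
runPipeline <- function(config = pipelineConfig(), outDir = config$outDir,
                        verbose = TRUE) {
  seed <- as.integer(config$seed)
  stopifnot(is.finite(seed))
  if (!is.null(outDir)) dir.create(outDir, showWarnings = FALSE,
                                   recursive = TRUE)
  dparams <- do.call(detectionParams, config$detection)
  stageMsg(verbose, "phantom: generating %d exams", config$nExams)
  crops <- list(); labels <- character(); examIds <- character()
  detSummary <- NULL
  for (i in seq_len(config$nExams)) {
    nTeeth <- config$teethPerRow[(i - 1) %% length(config$teethPerRow) + 1]
    spec <- do.call(phantomSpec, c(config$phantom,
                                   list(nTeethPerRow = nTeeth)))
    examId <- sprintf("exam%03d", i)
    ph <- generateBitewing(spec, seed = seed * 100L + i, examId = examId)
    regs <- detectTeeth(phantomImage(ph), dparams)
    mt <- matchRegionsToTruth(regs, ph, minIoU = config$matchIoU)
    detSummary <- rbind(detSummary, data.frame(
      examId = examId, nTruth = nrow(groundTruth(ph)),
      nDetected = length(regs), nMatched = nrow(mt),
      meanIoU = if (nrow(mt)) mean(mt$iou) else NA_real_))
    for (k in seq_len(nrow(mt))) {
      crops <- c(crops, list(regs@crops[[mt$regionIdx[k]]]))
      labels <- c(labels, groundTruth(ph)$label[mt$truthIdx[k]])
      examIds <- c(examIds, examId)
    }
    if (!is.null(outDir)) {
      writeGrayImage(phantomImage(ph),
                     file.path(outDir, paste0(examId, ".png")))
      writeGroundTruth(ph, file.path(outDir, paste0(examId, "_truth.json")))
      writeGrayImage(255 * (ph@toothMask > 0),
                     file.path(outDir, paste0(examId, "_mask.png")))
    }
  }
  allCrops <- toothCropSet(crops, labels, examIds)
  stageMsg(verbose, "detection: %d/%d teeth recovered (mean IoU %.2f)",
           sum(detSummary$nMatched), sum(detSummary$nTruth),
           mean(detSummary$meanIoU, na.rm = TRUE))
  sp <- splitByExam(allCrops, config$split$testPerClass, seed + 1L)
  stageMsg(verbose, "split: %d train / %d test crops (%d test exams)",
           length(sp$train), length(sp$test), length(sp$testExams))
  policy <- do.call(augmentPolicy, c(config$augment, list(seed = seed + 2L)))
  aug <- augmentTrainingSet(sp$train, policy)
  stageMsg(verbose, "augmentation: %d training images", length(aug))
  tconf <- do.call(trainConfig, c(config$train, list(seed = seed + 3L)))
  model <- buildModel(tconf)
  model <- trainModel(model, aug, holdoutExamIds = sp$testExams)
  stageMsg(verbose, "training: done%s",
           if (model@diverged) " (diverged)" else "")
  preds <- predictLabels(model, sp$test)
  scores <- predictProba(model, sp$test)
  evalRep <- evaluatePredictions(cropLabels(sp$test), preds, scores)
  modelCounts <- lesionsPerExam(cropExams(sp$test), preds)
  expertCounts <- lesionsPerExam(cropExams(sp$test), cropLabels(sp$test))
  agree <- list(
    incipient = wilcoxonSignedRank(modelCounts$incipient,
                                   expertCounts$incipient),
    advanced = wilcoxonSignedRank(modelCounts$advanced,
                                  expertCounts$advanced))
  report <- list(
    seed = seed,
    nExams = config$nExams,
    detection = detSummary,
    datasetCounts = as.list(table(cropLabels(allCrops))),
    trainCounts = as.list(table(cropLabels(sp$train))),
    augmentedCounts = as.list(table(cropLabels(aug))),
    nTest = length(sp$test),
    diverged = model@diverged,
    confusion = evalRep$confusion,
    metrics = evalRep$metrics,
    accuracy = evalRep$accuracy,
    auc = evalRep$auc,
    predictedCounts = as.list(evalRep$predictedCounts),
    perExam = list(model = modelCounts, expert = expertCounts),
    agreement = lapply(agree, function(a)
      a[c("statistic", "pValue", "n", "exact", "degenerate")]),
    minSampleSize = minSampleSizePaired(0.8, 0.05, 0.95))
  if (!is.null(outDir)) {
    labDf <- data.frame(examId = cropExams(allCrops),
                        label = as.character(cropLabels(allCrops)))
    write.csv(labDf, file.path(outDir, "labels.csv"), row.names = FALSE)
    for (i in seq_along(sp$test@crops))
      writeGrayImage(sp$test@crops[[i]],
                     file.path(outDir, sprintf("test_crop_%02d.png", i)))
    write.csv(trainingLog(model), file.path(outDir, "training_log.csv"),
              row.names = FALSE)
    saveModel(model, file.path(outDir, "model.rds"))
    jsonlite::write_json(report, file.path(outDir, "report.json"),
                         auto_unbox = TRUE, digits = 10, force = TRUE)
  }
  stageMsg(verbose, "evaluation: accuracy %.3f on %d test teeth",
           report$accuracy, report$nTest)
  report
}
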