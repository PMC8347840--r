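#' @title Severity classifier
#' @name classifier
#' @description A compact convolutional classifier over tooth crops with
#' three architectures: \code{tiny} (three conv blocks, global average
#' pooling, softmax head), \code{resnet_like} (stacked residual units, each
#' two convolutions and two ReLUs with an identity shortcut) and
#' \code{inception_like} (modules of parallel 1x1, 3x3 and 5x5 convolutions
#' plus a 3x3 max-pool branch, concatenated). Training uses momentum SGD
#' (coefficient 0.9), batch size 16 and categorical cross-entropy; class
#' balance is handled upstream by augmentation, not by loss weighting.
NULL

# First tiny block: a smoothing kernel replicated at nb intensity
# thresholds, so channel c carries ReLU(s1 * (mean3x3(x) - t_c)). The 1x1
# second block takes second differences of adjacent threshold channels,
# which yields tent-shaped radiodensity band detectors (occupancy of
# [t_{c}, t_{c+2}]) -- the radiographic feature that distinguishes lesion
# (dark), background and enamel pixels. Both blocks stay trainable; this
# is initialization, not a frozen feature extractor.
bandBlocks <- function(nb = 16, s1 = 8, lo = -0.48, hi = 0.44) {
  th <- seq(lo, hi, length.out = nb)
  dth <- diff(th)[1]
  l1 <- convLayer(3, 3, 1, nb)
  for (c in seq_len(nb)) l1$w[, , 1, c] <- s1 / 9
  l1$b <- -s1 * th
  nh <- nb - 2
  l2 <- convLayer(1, 1, nb, nh)
  l2$w[] <- 0
  for (c in seq_len(nh)) {
    l2$w[1, 1, c, c] <- 1 / (s1 * dth)
    l2$w[1, 1, c + 1, c] <- -2 / (s1 * dth)
    l2$w[1, 1, c + 2, c] <- 1 / (s1 * dth)
  }
  l2$b <- rep(0, nh)
  list(l1 = l1, l2 = l2, nh = nh)
}

# Layer stack per architecture. All stacks end with global average pooling,
# frozen feature standardization and a softmax head.
buildLayers <- function(config) {
  switch(config@architecture,
    tiny = {
      bb <- bandBlocks()
      # third block: identity passthrough of the band maps plus 4 freely
      # initialized mixing channels; average pooling preserves the area
      # fractions the bands measure (max pooling would erase small dark
      # lesion regions).
      l3 <- convLayer(3, 3, bb$nh, bb$nh + 4)
      for (c in seq_len(bb$nh)) {
        l3$w[, , , c] <- 0
        l3$w[2, 2, c, c] <- 1
      }
      # fine-tuning regime: the structured-initialized feature blocks are
      # frozen; the standardization and softmax head are trained.
      bb$l1$lrMult <- 0; bb$l2$lrMult <- 0; l3$lrMult <- 0
      list(bb$l1, bb$l2, avgPoolLayer(), l3, avgPoolLayer(), gapLayer(),
           featNormLayer(bb$nh + 4), denseLayer(bb$nh + 4, config@nClasses))
    },
    resnet_like = list(
      convLayer(3, 3, 1, 8),
      poolLayer(),
      residualLayer(8),
      residualLayer(8),
      residualLayer(8),
      gapLayer(),
      bnormLayer(8),
      denseLayer(8, config@nClasses)),
    inception_like = {
      i1 <- inceptionLayer(8, 4, 6, 4)     # -> 22 channels
      i2 <- inceptionLayer(i1$cout, 6, 8, 6)
      list(convLayer(3, 3, 1, 8), poolLayer(), i1, i2, gapLayer(),
           bnormLayer(i2$cout), denseLayer(i2$cout, config@nClasses))
    },
    stop("unknown architecture: ", config@architecture, call. = FALSE))
}

#' Build an untrained severity classifier
#'
#' Weight initialization is seeded from the configuration, so identical
#' configurations give identical models.
#'
#' @param config a \linkS4class{TrainConfig}.
#' @return An untrained \linkS4class{CariesModel}.
#' @export
#' @examples
#' buildModel(trainConfig())
buildModel <- function(config = trainConfig()) {
  validObject(config)
  layers <- withSeed(config@seed, buildLayers(config))
  new("CariesModel", architecture = config@architecture, config = config,
      layers = layers, classOrder = cariesStages(), trained = FALSE,
      diverged = FALSE, log = data.frame())
}

# Stack crops into the network input array [S, S, 1, n].
cropsToArray <- function(crops, size) {
  imgs <- if (is(crops, "ToothCropSet")) cropImages(crops) else crops
  n <- length(imgs)
  X <- array(0, dim = c(size, size, 1, n))
  for (i in seq_len(n)) X[, , 1, i] <- prepNetInput(imgs[[i]], size)
  X
}

#' Train the severity classifier
#'
#' Runs \code{iterations} momentum-SGD steps at the configured learning
#' rate with a stratified, seeded validation holdout used only for
#' accuracy logging. If the loss becomes non-finite (which large learning
#' rates can cause), training stops early, a \code{divergenceWarning} is
#' issued, and the last finite weights are kept so that evaluation can
#' still run; such models typically degenerate to a single-class
#' predictor.
#'
#' @param model an untrained (or previously trained) \linkS4class{CariesModel}.
#' @param crops training \linkS4class{ToothCropSet}.
#' @param config optional \linkS4class{TrainConfig} overriding the model's.
#' @param holdoutExamIds exam identifiers that must not appear in
#'   \code{crops}; an error is raised if any do (test-set leakage guard).
#' @return The trained \linkS4class{CariesModel} with its training log.
#' @export
trainModel <- function(model, crops, config = NULL, holdoutExamIds = NULL) {
  if (is.null(config)) config <- model@config
  validObject(config)
  if (!is.null(holdoutExamIds) &&
      any(cropExams(crops) %in% holdoutExamIds))
    stop("test-set leakage: training crops share exam ids with the holdout",
         call. = FALSE)
  labs <- cropLabels(crops)
  n <- length(crops)
  if (n < config@batchSize)
    stop("need at least batchSize training samples", call. = FALSE)
  y <- as.integer(labs)
  withSeed(config@seed, {
    X <- cropsToArray(crops, config@inputSize)
    # stratified validation holdout
    valIdx <- unlist(lapply(1:3, function(cl) {
      pool <- which(y == cl)
      k <- floor(length(pool) * config@validationFraction)
      if (k > 0) sample(pool, k) else integer()
    }))
    trainIdx <- setdiff(seq_len(n), valIdx)
    if (length(unique(y[trainIdx])) < 3)
      stop("every class must be present in the training portion",
           call. = FALSE)
    layers <- initFeatNorm(model@layers, X[, , , trainIdx, drop = FALSE])
    vel <- NULL
    if (config@pretrainSteps > 0) {
      warm <- generateLabeledCrops(
        c(normal = 60, incipient = 60, advanced = 60),
        cropSize = config@inputSize, seed = config@seed + 101L)
      wX <- cropsToArray(warm, config@inputSize)
      wy <- as.integer(cropLabels(warm))
      pre <- nnTrainLoop(layers, wX, wy, config@pretrainSteps,
                         config@learningRate, config@momentum,
                         config@batchSize)
      layers <- pre$layers
    }
    valX <- if (length(valIdx))
      X[, , , valIdx, drop = FALSE] else NULL
    res <- nnTrainLoop(layers, X[, , , trainIdx, drop = FALSE],
                       y[trainIdx], config@iterations, config@learningRate,
                       config@momentum, config@batchSize, vel = vel,
                       valX = valX, valY = y[valIdx])
    if (res$diverged)
      warning(warningCondition(
        "training loss became non-finite; stopped early with last finite weights",
        class = "divergenceWarning"))
    initialize(model, config = config, layers = res$layers, trained = TRUE,
               diverged = res$diverged, log = res$log)
  })
}

#' Class scores for tooth crops
#'
#' @param model a trained \linkS4class{CariesModel}.
#' @param crops a \linkS4class{ToothCropSet}, a list of matrices, or a
#'   single matrix.
#' @return Numeric matrix (n x 3), rows summing to 1, columns in
#'   \code{cariesStages()} order.
#' @export
predictProba <- function(model, crops) {
  if (!model@trained)
    stop("model is untrained; call trainModel() first", call. = FALSE)
  if (is.matrix(crops)) crops <- list(crops)
  X <- cropsToArray(crops, model@config@inputSize)
  p <- t(nnPredictProbs(model@layers, X))
  colnames(p) <- model@classOrder
  p
}

#' Predicted severity labels for tooth crops
#'
#' @inheritParams predictProba
#' @return Factor over \code{cariesStages()}; the argmax of
#'   \code{\link{predictProba}}.
#' @export
predictLabels <- function(model, crops) {
  p <- predictProba(model, crops)
  factor(cariesStages()[max.col(p, ties.method = "first")],
         levels = cariesStages())
}

#' Save / load a trained model
#'
#' Serializes the model (weights, configuration and class order) to a
#' single RDS file.
#'
#' @param model a \linkS4class{CariesModel}.
#' @param path file path.
#' @return \code{saveModel} invisibly returns \code{path};
#'   \code{loadModel} returns the \linkS4class{CariesModel}.
#' @export
saveModel <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname saveModel
#' @export
loadModel <- function(path) {
  m <- readRDS(path)
  if (!is(m, "CariesModel")) stop("not a serialized CariesModel",
                                  call. = FALSE)
  m
}
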