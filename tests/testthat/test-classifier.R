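smallCrops <- function(n = 20, size = 48, seed = 3)
  generateLabeledCrops(stats::setNames(rep(n, 3), cariesStages()),
                       cropSize = size, seed = seed)

test_that("built models expose the contracted shapes", {
  for (arch in c("tiny", "resnet_like", "inception_like")) {
    m <- buildModel(trainConfig(architecture = arch, inputSize = 48))
    expect_s4_class(m, "CariesModel")
    expect_false(m@trained)
    expect_identical(m@classOrder, cariesStages())
  }
  expect_error(trainConfig(architecture = "vgg"), "unknown architecture")
})

test_that("a residual unit with zeroed convolutions is the identity", {
  ru <- BitewingCaries:::residualLayer(4)
  ru$w1[] <- 0; ru$b1[] <- 0; ru$w2[] <- 0; ru$b2[] <- 0
  x <- array(abs(rnorm(10 * 10 * 4 * 2)), c(10, 10, 4, 2))
  out <- BitewingCaries:::nnForwardLayer(ru, x)$y
  expect_equal(out, x)
})

test_that("an inception module concatenates all four branches", {
  il <- BitewingCaries:::inceptionLayer(5, 2, 3, 4)
  x <- array(rnorm(12 * 12 * 5 * 2), c(12, 12, 5, 2))
  y <- BitewingCaries:::nnForwardLayer(il, x)$y
  expect_equal(dim(y), c(12, 12, 2 + 3 + 4 + 5, 2))
})

test_that("layer gradients agree with numerical differentiation", {
  ns <- asNamespace("BitewingCaries")
  set.seed(31)
  layers <- list(ns$convLayer(3, 3, 1, 2), ns$poolLayer(),
                 ns$residualLayer(2), ns$inceptionLayer(2, 2, 2, 2),
                 ns$gapLayer(), ns$denseLayer(8, 3))
  X <- array(rnorm(8 * 8 * 1 * 2), c(8, 8, 1, 2))
  y <- c(1L, 3L)
  fw <- ns$nnForward(layers, X)
  sl <- ns$softmaxLoss(fw$out, y)
  gr <- ns$nnBackward(layers, fw$caches, sl$dlogits)
  eps <- 1e-6
  for (i in seq_along(gr)) {
    g <- gr[[i]]
    if (is.null(g)) next
    for (p in names(g)) {
      for (k in sample(length(g[[p]]), min(3, length(g[[p]])))) {
        pert <- layers
        pert[[i]][[p]][k] <- pert[[i]][[p]][k] + eps
        lossP <- ns$softmaxLoss(ns$nnForward(pert, X)$out, y)$loss
        num <- (lossP - sl$loss) / eps
        expect_equal(as.vector(g[[p]])[k], num, tolerance = 1e-4)
      }
    }
  }
})

test_that("training is deterministic and logs its progress", {
  crops <- smallCrops(8, 40, seed = 5)
  cfg <- trainConfig(iterations = 40, inputSize = 40, seed = 7)
  m1 <- trainModel(buildModel(cfg), crops)
  m2 <- trainModel(buildModel(cfg), crops)
  expect_identical(trainingLog(m1), trainingLog(m2))
  expect_identical(predictProba(m1, crops[1:3]), predictProba(m2, crops[1:3]))
  expect_equal(nrow(trainingLog(m1)), 40)
  expect_true(m1@trained)
})

test_that("predictions are normalized, consistent and pure", {
  crops <- smallCrops(8, 40, seed = 6)
  m <- trainModel(buildModel(trainConfig(iterations = 30, inputSize = 40,
                                         seed = 2)), crops)
  p <- predictProba(m, crops)
  expect_equal(dim(p), c(length(crops), 3))
  expect_equal(rowSums(p), rep(1, length(crops)), tolerance = 1e-6)
  expect_true(all(p >= 0))
  labs <- predictLabels(m, crops)
  expect_identical(as.integer(labs), max.col(p, ties.method = "first"))
  expect_identical(predictProba(m, crops[1]), predictProba(m, crops[1]))
  expect_error(predictProba(buildModel(trainConfig()), crops), "untrained")
})

test_that("training guards against leakage, missing classes, small data", {
  crops <- smallCrops(8, 40, seed = 8)
  cfg <- trainConfig(iterations = 10, inputSize = 40)
  expect_error(
    trainModel(buildModel(cfg), crops,
               holdoutExamIds = cropExams(crops)[1]),
    "leakage")
  manyNormals <- smallCrops(18, 40, seed = 12)
  oneClass <- manyNormals[cropLabels(manyNormals) == "normal"]
  expect_error(trainModel(buildModel(cfg), oneClass), "every class")
  expect_error(trainModel(buildModel(cfg), crops[1:4]), "batchSize")
})

test_that("exploding training reports divergence but stays usable", {
  crops <- smallCrops(10, 40, seed = 9)
  cfg <- trainConfig(architecture = "resnet_like", learningRate = 1000,
                     iterations = 40, inputSize = 40, seed = 4)
  expect_warning(m <- trainModel(buildModel(cfg), crops),
                 class = "divergenceWarning")
  expect_true(m@diverged)
  p <- predictProba(m, crops[1:5])
  expect_true(all(is.finite(p)))
  expect_equal(rowSums(p), rep(1, 5), tolerance = 1e-6)
})

test_that("the phantom warm-up hook runs when requested", {
  crops <- smallCrops(8, 40, seed = 10)
  cfg <- trainConfig(iterations = 15, inputSize = 40, seed = 3,
                     pretrainSteps = 10)
  m <- trainModel(buildModel(cfg), crops)
  expect_true(m@trained)
  m2 <- trainModel(buildModel(cfg), crops)
  expect_identical(predictProba(m, crops[1:2]), predictProba(m2, crops[1:2]))
})

test_that("models survive serialization round trips", {
  crops <- smallCrops(8, 40, seed = 11)
  m <- trainModel(buildModel(trainConfig(iterations = 20, inputSize = 40,
                                         seed = 6)), crops)
  path <- tempfile(fileext = ".rds")
  saveModel(m, path)
  m2 <- loadModel(path)
  expect_identical(m2@classOrder, cariesStages())
  expect_identical(predictProba(m, crops[1:3]), predictProba(m2, crops[1:3]))
})
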