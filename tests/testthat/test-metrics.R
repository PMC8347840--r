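test_that("confusion matrices count true/predicted pairs correctly", {
  stages <- cariesStages()
  cm <- confusionMatrix(rep(stages, each = 15), rep(stages, each = 15))
  expect_equal(diag(cm), stats::setNames(rep(15L, 3), stages))
  expect_equal(sum(cm), 45)
  # a published benchmark matrix reconstructed from label vectors
  ref <- benchmarkMatrix("inception_0.001")
  lv <- labelsFromMatrix(ref)
  expect_equal(confusionMatrix(lv$true, lv$pred), ref)
  expect_error(confusionMatrix(character(), character()), "empty")
  expect_error(confusionMatrix("normal", c("normal", "advanced")), "length")
  expect_error(confusionMatrix("normal", "noclass"), "unknown")
})

test_that("per-class metrics reproduce the published benchmark tables", {
  for (model in benchmarkModels()) {
    got <- perClassMetrics(benchmarkMatrix(model))$byClass
    want <- benchmarkMetrics(model)
    for (metric in colnames(want))
      expect_lt(max(abs(got[[metric]] - want[, metric])), 0.0011,
                label = paste(model, metric, "max abs deviation"))
  }
  expect_equal(perClassMetrics(benchmarkMatrix("inception_0.001"))$accuracy,
               33 / 45)
})

test_that("degenerate single-class predictors report 0/0 ratios as zero", {
  m <- perClassMetrics(benchmarkMatrix("inception_0.1"))
  adv <- m$byClass[m$byClass$class == "advanced", ]
  expect_equal(adv$precision, 15 / 45)
  expect_equal(adv$specificity, 0)
  expect_equal(adv$npv, 0)               # 0/0 convention
  norm <- m$byClass[m$byClass$class == "normal", ]
  expect_equal(norm$precision, 0)        # 0/0 convention
  expect_equal(norm$specificity, 1)
})

test_that("perfect prediction yields unit metrics", {
  cm <- diag(3) * 15
  m <- perClassMetrics(cm)
  expect_true(all(as.matrix(m$byClass[, -1]) == 1))
  expect_equal(m$accuracy, 1)
  expect_error(perClassMetrics(matrix(0, 3, 3)), "all-zero")
})

test_that("Mann-Whitney AUC handles ties, separation and the null", {
  n <- 30
  yTrue <- rep(cariesStages(), each = 10)
  const <- matrix(1 / 3, n, 3)
  expect_equal(unname(rocAucOneVsRest(const, yTrue)$auc), rep(0.5, 3))
  perfect <- matrix(0, n, 3)
  perfect[cbind(seq_len(n), as.integer(factor(yTrue, cariesStages())))] <- 1
  expect_equal(unname(rocAucOneVsRest(perfect, yTrue)$auc), rep(1, 3))
  set.seed(20)
  aucs <- replicate(20, {
    s <- matrix(runif(200 * 3), 200, 3)
    mean(rocAucOneVsRest(s / rowSums(s), rep(cariesStages(), len = 200))$auc)
  })
  expect_lt(abs(mean(aucs) - 0.5), 0.1)
  expect_error(rocAucOneVsRest(const, rep("normal", n)), "undefined AUC")
})

test_that("rank AUC equals the trapezoidal ROC area", {
  set.seed(21)
  for (i in 1:20) {
    n <- sample(10:50, 1)
    yTrue <- sample(cariesStages(), n, replace = TRUE)
    while (length(unique(yTrue)) < 3)
      yTrue <- sample(cariesStages(), n, replace = TRUE)
    scores <- matrix(round(runif(n * 3), 2), n, 3)    # rounding forces ties
    res <- rocAucOneVsRest(scores, yTrue)
    for (c in 1:3)
      expect_equal(res$auc[[c]],
                   trapezoidAUC(scores[, c], yTrue == cariesStages()[c]))
  }
})

test_that("rank AUC matches an established implementation", {
  skip_if_not_installed("pROC")
  set.seed(22)
  yTrue <- sample(cariesStages(), 60, replace = TRUE)
  scores <- matrix(runif(180), 60, 3)
  res <- rocAucOneVsRest(scores, yTrue)
  for (c in 1:3) {
    ref <- pROC::auc(pROC::roc(response = yTrue == cariesStages()[c],
                               predictor = scores[, c], quiet = TRUE,
                               direction = "<"))
    expect_equal(res$auc[[c]], as.numeric(ref))
  }
})

test_that("predicted lesion counts are confusion-matrix column sums", {
  counts <- predictedLesionCounts(benchmarkMatrix("inception_0.001"))
  expect_equal(counts[["incipient"]], 18)
  expect_equal(counts[["advanced"]], 16)
  cm <- diag(3) * 7
  expect_equal(unname(predictedLesionCounts(cm)), rep(7, 3))
  expect_equal(unname(predictedLesionCounts(matrix(0, 3, 3))), rep(0, 3))
})

test_that("evaluatePredictions assembles a coherent report", {
  lv <- labelsFromMatrix(benchmarkMatrix("resnet_0.01"))
  rep <- evaluatePredictions(lv$true, lv$pred)
  expect_equal(rep$confusion, benchmarkMatrix("resnet_0.01"))
  expect_equal(rep$accuracy, sum(diag(benchmarkMatrix("resnet_0.01"))) / 45)
  expect_equal(rep$predictedCounts[["advanced"]], 7)
})
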