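test_that("splitDataset draws exact per-class test sets without overlap", {
  crops <- generateLabeledCrops(c(normal = 20, incipient = 16, advanced = 16),
                                cropSize = 32, seed = 1)
  sp <- splitDataset(crops, splitSpec(testPerClass = 3, seed = 5))
  expect_equal(as.vector(table(cropLabels(sp$test))), c(3, 3, 3))
  expect_equal(as.vector(table(cropLabels(sp$train))), c(17, 13, 13))
  expect_length(intersect(cropExams(sp$train), cropExams(sp$test)), 0)
  # determinism
  sp2 <- splitDataset(crops, splitSpec(testPerClass = 3, seed = 5))
  expect_identical(cropExams(sp$test), cropExams(sp2$test))
  # zero test set
  sp0 <- splitDataset(crops, splitSpec(testPerClass = 0, seed = 5))
  expect_length(sp0$test, 0)
  expect_length(sp0$train, length(crops))
  expect_error(splitDataset(crops, splitSpec(testPerClass = 17, seed = 1)),
               "split error")
})

test_that("a 15-per-class holdout of a 480-tooth cohort leaves 290/98/47", {
  crops <- generateLabeledCrops(c(normal = 305, incipient = 113,
                                  advanced = 62), cropSize = 32, seed = 9)
  sp <- splitDataset(crops, splitSpec(testPerClass = 15, seed = 1))
  expect_equal(as.vector(table(cropLabels(sp$train))), c(290, 98, 47))
  expect_equal(length(sp$test), 45)
})

test_that("transforms are exact where exactness is promised", {
  crops <- generateLabeledCrops(c(normal = 1, incipient = 0, advanced = 0),
                                cropSize = 64, seed = 2, noiseSd = 0)
  m <- cropImages(crops)[[1]]
  expect_identical(applyTransform(m, FALSE, 0), m)
  expect_identical(applyTransform(applyTransform(m, TRUE, 0), TRUE, 0), m)
  expect_equal(dim(applyTransform(m, TRUE, 10)), dim(m))
  expect_error(applyTransform(m, FALSE, 95), "angle")
})

test_that("rotation round trip stays within interpolation tolerance", {
  crops <- generateLabeledCrops(c(normal = 2, incipient = 0, advanced = 1),
                                cropSize = 64, seed = 3, noiseSd = 0)
  for (m in cropImages(crops)) {
    rt <- applyTransform(applyTransform(m, FALSE, 10), FALSE, -10)
    expect_lt(mean(abs(rt - m)), 3)
  }
})

test_that("augmentation multiplies each class exactly", {
  crops <- generateLabeledCrops(c(normal = 5, incipient = 3, advanced = 2),
                                cropSize = 32, seed = 4)
  aug <- augmentTrainingSet(crops, augmentPolicy())
  expect_equal(as.vector(table(cropLabels(aug))),
               c(5 * 4, 3 * 12, 2 * 24))
  # multiplicity one returns the inputs untouched
  one <- augmentPolicy(multiplicity = c(normal = 1, incipient = 1,
                                        advanced = 1))
  id <- augmentTrainingSet(crops, one)
  expect_identical(cropImages(id), cropImages(crops))
  # label and exam conservation on every output
  labs <- as.character(cropLabels(crops))
  mult <- c(normal = 4, incipient = 12, advanced = 24)
  expect_identical(as.character(cropLabels(aug)), rep(labs, mult[labs]))
  expect_identical(cropExams(aug), rep(cropExams(crops), mult[labs]))
  # determinism under the policy seed
  aug2 <- augmentTrainingSet(crops, augmentPolicy())
  expect_identical(cropImages(aug), cropImages(aug2))
  expect_error(augmentTrainingSet(crops[0], augmentPolicy()), "empty")
})

test_that("count identity holds for arbitrary multiplicities", {
  crops <- generateLabeledCrops(c(normal = 4, incipient = 4, advanced = 4),
                                cropSize = 32, seed = 6)
  set.seed(10)
  for (i in 1:4) {
    mult <- stats::setNames(sample(1:15, 3, replace = TRUE), cariesStages())
    aug <- augmentTrainingSet(crops, augmentPolicy(multiplicity = mult))
    expect_equal(as.vector(table(cropLabels(aug))), as.vector(4 * mult))
  }
})

test_that("jittered pool reuse produces distinct extra variants", {
  crops <- generateLabeledCrops(c(normal = 0, incipient = 0, advanced = 1),
                                cropSize = 32, seed = 7)
  aug <- augmentTrainingSet(crops, augmentPolicy())   # advanced: 24 copies
  imgs <- cropImages(aug)
  expect_length(imgs, 24)
  # the 10 pool entries are exact; the 14 jittered reuses differ from them
  expect_identical(imgs[[1]], cropImages(crops)[[1]])
  dup <- sum(duplicated(lapply(imgs, function(m) round(m, 6))))
  expect_equal(dup, 0)
})
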