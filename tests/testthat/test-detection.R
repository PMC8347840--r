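twoBandImage <- function(a, b, sdn, seed = 1) {
  set.seed(seed)
  img <- cbind(matrix(a, 160, 80), matrix(b, 160, 80)) +
    matrix(rnorm(160 * 160, 0, sdn), 160)
  pmin(pmax(img, 0), 255)
}

test_that("adaptive equalization preserves shape and flat images", {
  flat <- matrix(128, 120, 150)
  eq <- adaptiveEqualize(flat)
  expect_equal(dim(eq), dim(flat))
  expect_lt(diff(range(eq)), 1e-8)   # constant in, constant out
  img <- twoBandImage(100, 150, 4)
  expect_equal(dim(adaptiveEqualize(img)), dim(img))
  expect_error(adaptiveEqualize(matrix(1, 4, 4)), "too small")
})

test_that("equalization increases separation across a low-contrast edge", {
  for (bands in list(c(118, 124, 2), c(100, 115, 4), c(200, 215, 4))) {
    img <- twoBandImage(bands[1], bands[2], bands[3])
    eq <- adaptiveEqualize(img)
    sepBefore <- mean(img[, 81:90]) - mean(img[, 71:80])
    sepAfter <- mean(eq[, 81:90]) - mean(eq[, 71:80])
    expect_gt(sepAfter, sepBefore)
  }
})

test_that("Otsu threshold separates a two-level image exactly", {
  img <- matrix(c(rep(50, 500), rep(200, 500)), 25, 40)
  res <- otsuThreshold(img)
  expect_gte(res$threshold, 50)
  expect_lt(res$threshold, 200)
  expect_identical(res$mask, img == 200)
  expect_error(otsuThreshold(matrix(7, 5, 5)), "degenerate")
})

test_that("Otsu threshold maximizes between-class variance", {
  set.seed(4)
  for (i in 1:6) {
    img <- matrix(round(c(rnorm(400, 70, 15), rnorm(400, 180, 20))), 40, 20)
    img <- pmin(pmax(img, 0), 255)
    res <- otsuThreshold(img)
    achieved <- otsuVarianceAt(img, res$threshold)
    expect_gte(achieved, otsuOracleMaxVariance(img) * (1 - 1e-6))
  }
})

test_that("thresholding a phantom recovers the tooth-pixel fraction", {
  ph <- generateBitewing(phantomSpec(nTeethPerRow = 4), seed = 5)
  res <- otsuThreshold(phantomImage(ph))
  truthFrac <- mean(ph@toothMask > 0)
  expect_lt(abs(mean(res$mask) - truthFrac), 0.05)
})

test_that("morphological refinement removes speckle and keeps teeth", {
  allFalse <- matrix(FALSE, 120, 160)
  expect_true(all(!morphologicalRefine(allFalse)))
  # one large solid rectangle stays one component
  big <- matrix(FALSE, 300, 400)
  big[50:250, 80:330] <- TRUE
  out <- morphologicalRefine(big)
  expect_equal(max(BitewingCaries:::cc_label8(out)), 1)
  # phantom mask plus salt speckles: speckles die, every tooth survives
  ph <- generateBitewing(phantomSpec(nTeethPerRow = 3), seed = 6)
  mask <- ph@toothMask > 0
  set.seed(1)
  salt <- sample(length(mask), 150)
  mask[salt] <- TRUE
  refined <- morphologicalRefine(mask)
  expect_equal(max(BitewingCaries:::cc_label8(refined)),
               nrow(groundTruth(ph)))
  tight <- detectionParams(referenceResolution = c(40, 30))
  expect_error(morphologicalRefine(matrix(TRUE, 20, 10), tight),
               "structuring element")
})

test_that("erosion is anti-extensive, dilation extensive, opening idempotent", {
  disk <- BitewingCaries:::diskKernel(3)
  set.seed(8)
  for (i in 1:10) {
    m <- matrix(runif(80 * 90) < 0.4, 80, 90)
    er <- BitewingCaries:::ebErode(m + 0, disk)
    di <- BitewingCaries:::ebDilate(m + 0, disk)
    expect_true(all(!er | m))          # erosion subset of input
    expect_true(all(!m | di))          # input subset of dilation
    op1 <- BitewingCaries:::ebDilate(er + 0, disk)
    op2 <- BitewingCaries:::ebDilate(
      BitewingCaries:::ebErode(op1 + 0, disk) + 0, disk)
    expect_identical(op1, op2)         # opening is idempotent
  }
})

test_that("extractToothRegions filters by area and orders regions", {
  img <- matrix(10, 200, 300)
  expect_length(extractToothRegions(matrix(FALSE, 200, 300), img), 0)
  mask <- matrix(FALSE, 200, 300)
  mask[20:90, 30:100] <- TRUE          # blob 1
  mask[120:190, 180:260] <- TRUE       # blob 2
  mask[5:6, 290:291] <- TRUE           # speck below the area floor
  regs <- extractToothRegions(mask, img)
  expect_length(regs, 2)
  bb <- bboxes(regs)
  expect_true(all(diff(bb[, "c0"]) > 0))            # left-to-right order
  expect_equal(regionAreas(regs), c(71 * 71, 71 * 81))
  expect_equal(dim(regs@crops[[1]]), c(71, 71))     # crop matches bbox
})

test_that("detectTeeth recovers phantom teeth with tight boxes", {
  ph <- generateBitewing(phantomSpec(rows = 2, nTeethPerRow = 3), seed = 7)
  regs <- detectTeeth(phantomImage(ph))
  expect_length(regs, 6)
  mt <- matchRegionsToTruth(regs, ph)
  expect_equal(nrow(mt), 6)
  expect_true(all(mt$iou >= 0.5))
  # determinism and composition against the staged calls
  regs2 <- detectTeeth(phantomImage(ph))
  expect_identical(bboxes(regs), bboxes(regs2))
  eq <- adaptiveEqualize(phantomImage(ph))
  staged <- extractToothRegions(
    morphologicalRefine(otsuThreshold(eq)$mask), phantomImage(ph))
  expect_identical(bboxes(regs), bboxes(staged))
  expect_error(detectTeeth(matrix(100, 600, 800)), "degenerate")
})

test_that("detected regions serialize to JSON and CSV", {
  ph <- generateBitewing(phantomSpec(nTeethPerRow = 3), seed = 11)
  regs <- detectTeeth(phantomImage(ph))
  jp <- tempfile(fileext = ".json"); cp <- tempfile(fileext = ".csv")
  writeToothRegions(regs, jp, cp)
  expect_length(jsonlite::read_json(jp), length(regs))
  expect_equal(nrow(utils::read.csv(cp)), length(regs))
})
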