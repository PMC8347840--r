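test_that("lesionsPerExam counts incipient and advanced calls per exam", {
  out <- lesionsPerExam(rep("e1", 4),
                        c("normal", "incipient", "advanced", "advanced"))
  expect_equal(out$incipient, 1L)
  expect_equal(out$advanced, 2L)
  expect_equal(nrow(lesionsPerExam(character(), character())), 0)
  expect_error(lesionsPerExam("e1", "bogus"), "unknown")
})

test_that("per-exam totals agree with confusion-matrix column sums", {
  set.seed(30)
  exams <- sample(sprintf("e%02d", 1:24), 45, replace = TRUE)
  yTrue <- rep(cariesStages(), each = 15)
  yPred <- sample(cariesStages(), 45, replace = TRUE)
  counts <- lesionsPerExam(exams, yPred)
  cm <- confusionMatrix(yTrue, yPred)
  expect_equal(sum(counts$incipient),
               unname(predictedLesionCounts(cm)[["incipient"]]))
  expect_equal(sum(counts$advanced),
               unname(predictedLesionCounts(cm)[["advanced"]]))
})

test_that("degenerate and tied signed-rank cases follow their contracts", {
  same <- wilcoxonSignedRank(c(2, 3, 1), c(2, 3, 1))
  expect_equal(same$pValue, 1)
  expect_true(same$degenerate)
  # all differences -1: tied |d|, statistic 0, approximate branch
  x <- 1:5; y <- 2:6
  res <- wilcoxonSignedRank(x, y)
  expect_equal(res$statistic, 0)
  expect_false(res$exact)
  ref <- suppressWarnings(stats::wilcox.test(x, y, paired = TRUE))
  expect_equal(res$pValue, ref$p.value)
  expect_error(wilcoxonSignedRank(1:3, 1:4), "length")
})

test_that("exact p-values equal the sign-enumeration oracle", {
  set.seed(31)
  for (i in 1:60) {
    n <- sample(3:10, 1)
    d <- sample(1:50, n) * sample(c(-1, 1), n, replace = TRUE)
    x <- rpois(n, 4) + pmax(d, 0)
    y <- x - d
    res <- wilcoxonSignedRank(x, y)
    expect_true(res$exact)
    expect_equal(res$pValue, signedRankEnumOracle(x, y))
  }
})

test_that("the test is symmetric and its p-values lie in (0, 1]", {
  set.seed(32)
  for (i in 1:20) {
    x <- rpois(8, 3); y <- rpois(8, 3)
    if (all(x == y)) next
    a <- wilcoxonSignedRank(x, y)
    b <- wilcoxonSignedRank(y, x)
    expect_equal(a$pValue, b$pValue)
    expect_equal(a$statistic, b$statistic)
    expect_gt(a$pValue, 0)
    expect_lte(a$pValue, 1)
  }
})

test_that("zero retention (Pratt) is available and sane", {
  x <- c(3, 3, 2, 5, 1); y <- c(3, 1, 2, 2, 4)
  res <- wilcoxonSignedRank(x, y, zeroMethod = "pratt")
  expect_false(res$exact)
  expect_gt(res$pValue, 0)
  expect_lte(res$pValue, 1)
})

test_that("minimum paired sample size reproduces the published value", {
  expect_equal(minSampleSizePaired(0.8, 0.05, 0.95), 22L)
  # ceiling mode returns the smallest n whose power meets the target
  nCeil <- minSampleSizePaired(0.8, 0.05, 0.95, rounding = "ceiling")
  pow <- BitewingCaries:::pairedTPower(nCeil, 0.8, 0.05)
  expect_gte(pow, 0.95)
  expect_lt(BitewingCaries:::pairedTPower(nCeil - 1, 0.8, 0.05), 0.95)
})

test_that("sample size is monotone in power and effect size", {
  expect_gt(minSampleSizePaired(0.8, 0.05, 0.999),
            minSampleSizePaired(0.8, 0.05, 0.95))
  expect_gt(minSampleSizePaired(0.4, 0.05, 0.95),
            minSampleSizePaired(0.8, 0.05, 0.95))
  expect_error(minSampleSizePaired(0), "effectSize")
  expect_error(minSampleSizePaired(0.8, power = 1.2), "power")
})

test_that("the noncentral-t solution matches its approximations", {
  # large n: within 2 of the closed-form normal approximation
  d <- 0.1
  approx <- ((qnorm(0.975) + qnorm(0.95)) / d)^2
  expect_lt(abs(minSampleSizePaired(d, 0.05, 0.95) - approx), 2 + 1)
  # continuous solution agrees with the established power solver
  ref <- stats::power.t.test(delta = 0.8, sd = 1, sig.level = 0.05,
                             power = 0.95, type = "paired")$n
  expect_equal(minSampleSizePaired(0.8, 0.05, 0.95), as.integer(floor(ref)))
})
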