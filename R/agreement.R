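#' @title Reader agreement and power analysis
#' @name agreement
#' @description Per-exam lesion counting, paired Wilcoxon signed-rank tests
#' comparing the model's per-exam counts with a reference rater's, and the
#' minimum sample size for a two-sided paired t-test at a given standardized
#' effect size.
NULL

#' Count predicted lesions per exam
#'
#' Counts incipient and advanced predictions per exam; teeth called normal
#' are not lesions and are not counted.
#'
#' @param examIds exam identifier per prediction.
#' @param predicted predicted class per tooth (values in
#'   \code{cariesStages()}).
#' @return data.frame with columns \code{examId}, \code{incipient},
#'   \code{advanced}, one row per exam (exam order of first appearance).
#' @export
#' @examples
#' lesionsPerExam(c("e1", "e1", "e1", "e1"),
#'                c("normal", "incipient", "advanced", "advanced"))
lesionsPerExam <- function(examIds, predicted) {
  if (length(examIds) != length(predicted))
    stop("examIds and predicted must have equal length", call. = FALSE)
  if (length(examIds) == 0)
    return(data.frame(examId = character(), incipient = integer(),
                      advanced = integer()))
  predicted <- as.character(predicted)
  if (!all(predicted %in% cariesStages()))
    stop("unknown class label", call. = FALSE)
  ids <- unique(as.character(examIds))
  data.frame(
    examId = ids,
    incipient = vapply(ids, function(e)
      sum(examIds == e & predicted == "incipient"), 1L),
    advanced = vapply(ids, function(e)
      sum(examIds == e & predicted == "advanced"), 1L),
    row.names = NULL)
}

#' Paired Wilcoxon signed-rank test
#'
#' Tests whether paired counts differ. Differences of zero are dropped by
#' default (\code{zeroMethod = "drop"}) or retained Pratt-style
#' (\code{"pratt"}). Absolute differences are ranked with average ranks for
#' ties; the reported statistic is the smaller of the positive- and
#' negative-rank sums. The two-sided p-value is exact (signed-rank null
#' distribution) when the effective n is at most 25 and there are no ties
#' under \code{"drop"}; otherwise a normal approximation with tie
#' correction and continuity correction is used. If every difference is
#' zero the test is degenerate and p = 1.
#'
#' @param x,y paired numeric vectors (e.g. per-exam lesion counts of two
#'   raters).
#' @param zeroMethod \code{"drop"} (default) or \code{"pratt"}.
#' @param exactLimit largest effective n for the exact branch.
#' @return List with \code{statistic}, \code{pValue}, \code{n} (effective),
#'   \code{exact} and \code{degenerate} flags.
#' @export
#' @examples
#' wilcoxonSignedRank(c(1, 2, 0, 3), c(0, 2, 1, 1))
wilcoxonSignedRank <- function(x, y, zeroMethod = c("drop", "pratt"),
                               exactLimit = 25) {
  zeroMethod <- match.arg(zeroMethod)
  if (length(x) != length(y))
    stop("x and y must have equal length", call. = FALSE)
  if (length(x) < 1) stop("need at least one pair", call. = FALSE)
  d <- x - y
  nZero <- sum(d == 0)
  if (all(d == 0))
    return(list(statistic = 0, pValue = 1, n = 0L, exact = FALSE,
                degenerate = TRUE))
  if (zeroMethod == "drop") {
    d <- d[d != 0]
    r <- rank(abs(d))
    nEff <- length(d)
    wPos <- sum(r[d > 0]); wNeg <- sum(r[d < 0])
    mu <- nEff * (nEff + 1) / 4
    ties <- table(r)
    sigma2 <- nEff * (nEff + 1) * (2 * nEff + 1) / 24 -
      sum(ties^3 - ties) / 48
    hasTies <- any(ties > 1)
  } else {
    # Pratt: rank |d| including zeros, then discard the zero ranks.
    r <- rank(abs(d))
    nAll <- length(d)
    wPos <- sum(r[d > 0]); wNeg <- sum(r[d < 0])
    nEff <- nAll - nZero
    mu <- (nAll * (nAll + 1) - nZero * (nZero + 1)) / 4
    ties <- table(r[d != 0])
    sigma2 <- (nAll * (nAll + 1) * (2 * nAll + 1) -
               nZero * (nZero + 1) * (2 * nZero + 1)) / 24 -
      sum(ties^3 - ties) / 48
    hasTies <- TRUE                    # zeros force the approximate branch
  }
  stat <- min(wPos, wNeg)
  exact <- !hasTies && nEff <= exactLimit
  if (exact) {
    p <- if (wPos == wNeg) 1 else min(1, 2 * psignrank(stat, nEff))
  } else {
    z <- (stat - mu + 0.5) / sqrt(sigma2)
    p <- min(1, 2 * pnorm(z))
  }
  list(statistic = stat, pValue = p, n = as.integer(nEff), exact = exact,
       degenerate = FALSE)
}

# Power of a two-sided paired t-test with n pairs at standardized effect d.
pairedTPower <- function(n, d, alpha) {
  df <- n - 1
  tc <- qt(1 - alpha / 2, df)
  ncp <- d * sqrt(n)
  pt(tc, df, ncp = ncp, lower.tail = FALSE) + pt(-tc, df, ncp = ncp)
}

#' Minimum sample size for a paired t-test
#'
#' Solves the noncentral-t power equation
#' \eqn{power(n) = P(|T_{n-1}(d\sqrt{n})| > t_{1-\alpha/2, n-1})} for
#' continuous n and returns its integer part (\code{rounding =
#' "truncate"}, the default) or the smallest integer n whose power meets
#' the target (\code{"ceiling"}).
#'
#' @param effectSize standardized paired effect size (Cohen's d), > 0.
#' @param alpha two-sided significance level.
#' @param power target power in (0, 1).
#' @param rounding \code{"truncate"} or \code{"ceiling"}.
#' @return Integer number of pairs.
#' @export
#' @examples
#' minSampleSizePaired(effectSize = 0.8, alpha = 0.05, power = 0.95)
minSampleSizePaired <- function(effectSize, alpha = 0.05, power = 0.95,
                                rounding = c("truncate", "ceiling")) {
  rounding <- match.arg(rounding)
  if (!is.finite(effectSize) || effectSize <= 0)
    stop("effectSize must be > 0", call. = FALSE)
  if (alpha <= 0 || alpha >= 1 || power <= 0 || power >= 1)
    stop("alpha and power must lie in (0, 1)", call. = FALSE)
  f <- function(n) pairedTPower(n, effectSize, alpha) - power
  nStar <- uniroot(f, c(2 + 1e-9, 1e7), tol = 1e-9)$root
  as.integer(if (rounding == "truncate") floor(nStar) else ceiling(nStar))
}
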