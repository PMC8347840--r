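#' @title Diagnostic evaluation metrics
#' @name metrics
#' @description One-vs-rest evaluation of a 3-class severity classifier:
#' confusion matrices (rows = true class, columns = predicted class, fixed
#' class order), per-class precision/recall/specificity/NPV with overall
#' accuracy, Mann-Whitney ROC AUC from class scores, and per-predicted-class
#' lesion counts. Ratios with an empty denominator (0/0) are reported as 0,
#' the convention a degenerate single-class predictor produces in published
#' metric tables.
NULL

#' Build a 3-class confusion matrix
#'
#' @param yTrue,yPred vectors of class labels (values in
#'   \code{cariesStages()}).
#' @return 3x3 integer matrix; entry (i, j) counts items of true class i
#'   predicted as class j.
#' @export
#' @examples
#' confusionMatrix(rep(cariesStages(), 5), rep(cariesStages(), 5))
confusionMatrix <- function(yTrue, yPred) {
  if (length(yTrue) != length(yPred))
    stop("yTrue and yPred must have equal length", call. = FALSE)
  if (length(yTrue) == 0) stop("empty label vectors", call. = FALSE)
  stages <- cariesStages()
  yTrue <- as.character(yTrue); yPred <- as.character(yPred)
  if (!all(yTrue %in% stages) || !all(yPred %in% stages))
    stop("unknown class label", call. = FALSE)
  cm <- table(factor(yTrue, levels = stages), factor(yPred, levels = stages))
  m <- matrix(as.integer(cm), 3, 3,
              dimnames = list(true = stages, predicted = stages))
  m
}

div0 <- function(num, den) if (den == 0) 0 else num / den

#' Per-class diagnostic metrics from a confusion matrix
#'
#' One-vs-rest decomposition per class c: TP = cm[c, c], FP = column sum
#' minus TP, FN = row sum minus TP, TN = remainder. Precision = TP/(TP+FP),
#' recall (sensitivity) = TP/(TP+FN), specificity = TN/(TN+FP),
#' NPV = TN/(TN+FN); 0/0 ratios are reported as 0. Overall accuracy is
#' trace/total.
#'
#' @param cm 3x3 confusion matrix (rows = true, columns = predicted).
#' @return List with \code{byClass} (data.frame: class, precision, recall,
#'   specificity, npv) and \code{accuracy}.
#' @export
#' @examples
#' cm <- confusionMatrix(rep(cariesStages(), each = 5),
#'                       rep(cariesStages(), each = 5))
#' perClassMetrics(cm)$accuracy
perClassMetrics <- function(cm) {
  cm <- as.matrix(cm)
  if (!all(dim(cm) == c(3, 3)) || any(cm < 0))
    stop("cm must be a non-negative 3x3 matrix", call. = FALSE)
  total <- sum(cm)
  if (total == 0) stop("all-zero confusion matrix", call. = FALSE)
  stages <- cariesStages()
  by <- do.call(rbind, lapply(seq_len(3), function(c) {
    tp <- cm[c, c]
    fp <- sum(cm[, c]) - tp
    fn <- sum(cm[c, ]) - tp
    tn <- total - tp - fp - fn
    data.frame(class = stages[c],
               precision = div0(tp, tp + fp),
               recall = div0(tp, tp + fn),
               specificity = div0(tn, tn + fp),
               npv = div0(tn, tn + fn),
               stringsAsFactors = FALSE)
  }))
  list(byClass = by, accuracy = sum(diag(cm)) / total)
}

#' One-vs-rest ROC AUC from class scores
#'
#' For each class, AUC is the Mann-Whitney probability that a random item of
#' that class receives a higher class score than a random item of any other
#' class, with ties counted 1/2. ROC curve points are returned for plotting.
#'
#' @param scores numeric matrix (items x 3), columns in
#'   \code{cariesStages()} order.
#' @param yTrue true class labels, aligned with \code{scores} rows.
#' @return List with \code{auc} (named numeric) and \code{curves} (named
#'   list of data.frames with \code{fpr}, \code{tpr}).
#' @export
rocAucOneVsRest <- function(scores, yTrue) {
  scores <- as.matrix(scores)
  if (nrow(scores) != length(yTrue) || ncol(scores) != 3)
    stop("scores must be (length(yTrue) x 3)", call. = FALSE)
  stages <- cariesStages()
  yTrue <- as.character(yTrue)
  auc <- stats::setNames(numeric(3), stages)
  curves <- stats::setNames(vector("list", 3), stages)
  for (c in seq_len(3)) {
    pos <- yTrue == stages[c]
    nPos <- sum(pos); nNeg <- sum(!pos)
    if (nPos == 0 || nNeg == 0)
      stop("undefined AUC: class '", stages[c],
           "' lacks positives or negatives", call. = FALSE)
    s <- scores[, c]
    r <- rank(s)                        # average ranks handle ties as 1/2
    auc[c] <- (sum(r[pos]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
    ths <- sort(unique(s), decreasing = TRUE)
    tpr <- vapply(ths, function(t) mean(s[pos] >= t), 1)
    fpr <- vapply(ths, function(t) mean(s[!pos] >= t), 1)
    curves[[c]] <- data.frame(fpr = c(0, fpr), tpr = c(0, tpr))
  }
  list(auc = auc, curves = curves)
}

#' Predicted lesion counts per class
#'
#' Column sums of a confusion matrix: how many teeth the model called
#' normal, incipient and advanced in total.
#'
#' @param cm 3x3 confusion matrix (rows = true, columns = predicted).
#' @return Named integer vector over \code{cariesStages()}.
#' @export
predictedLesionCounts <- function(cm) {
  cm <- as.matrix(cm)
  if (!all(dim(cm) == c(3, 3)) || any(cm < 0))
    stop("cm must be a non-negative 3x3 matrix", call. = FALSE)
  stats::setNames(colSums(cm), cariesStages())
}

#' Evaluate predictions into a report
#'
#' Convenience wrapper producing the confusion matrix, per-class metrics,
#' AUCs and predicted lesion counts in one list (JSON-serializable).
#'
#' @param yTrue true labels.
#' @param yPred predicted labels.
#' @param scores optional (items x 3) score matrix for AUC.
#' @return List with \code{confusion}, \code{metrics}, \code{accuracy},
#'   \code{predictedCounts} and (if scores given) \code{auc}.
#' @export
evaluatePredictions <- function(yTrue, yPred, scores = NULL) {
  cm <- confusionMatrix(yTrue, yPred)
  pm <- perClassMetrics(cm)
  out <- list(confusion = cm, metrics = pm$byClass, accuracy = pm$accuracy,
              predictedCounts = predictedLesionCounts(cm))
  if (!is.null(scores)) {
    roc <- tryCatch(rocAucOneVsRest(scores, yTrue), error = function(e) NULL)
    if (!is.null(roc)) out$auc <- roc$auc
  }
  out
}
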