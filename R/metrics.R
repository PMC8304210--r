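# One-vs-rest classification metrics from a confusion matrix, and ROC/AUC.

#' Published clinical-validation confusion matrix
#'
#' The printed 6 x 6 confusion matrix (true class x predicted class) of the
#' compact classifier on the clinical test set: 1,361 cells, 11
#' misclassifications, promyelocyte sensitivity 125/126. Shipped as the
#' reference input for the metric layer's verification and examples.
#'
#' @return Integer matrix with \code{LEUKOCYTE_CLASSES} dimnames.
#' @examples
#' metricsFromConfusion(clinicalConfusionMatrix())$weighted
#' @export
clinicalConfusionMatrix <- function() {
  matrix(c(190, 0, 0, 0, 0, 0,
           1, 210, 1, 0, 0, 0,
           0, 0, 191, 2, 2, 0,
           0, 0, 1, 180, 1, 0,
           0, 0, 0, 1, 125, 0,
           0, 0, 0, 2, 0, 454),
         nrow = 6, byrow = TRUE,
         dimnames = list(true = LEUKOCYTE_CLASSES,
                         predicted = LEUKOCYTE_CLASSES))
}

#' Six-class confusion matrix
#'
#' counts[i, j] is the number of samples with true class i predicted as class
#' j; rows and columns follow \code{LEUKOCYTE_CLASSES}.
#'
#' @param yTrue,yPred equal-length label vectors (factor or character) over
#'   the six classes.
#' @param classes class vocabulary (default \code{LEUKOCYTE_CLASSES}).
#' @return Integer matrix with dimnames (true x predicted).
#' @examples
#' confusionMatrix6(rep(LEUKOCYTE_CLASSES, 2), rep(LEUKOCYTE_CLASSES, 2))
#' @export
confusionMatrix6 <- function(yTrue, yPred, classes = LEUKOCYTE_CLASSES) {
  yTrue <- as.character(yTrue); yPred <- as.character(yPred)
  if (length(yTrue) != length(yPred))
    stop("yTrue and yPred must have equal length")
  bad <- setdiff(unique(c(yTrue, yPred)), classes)
  if (length(bad) > 0L)
    stop(sprintf("unknown class label '%s'", bad[1]))
  k <- length(classes)
  cm <- matrix(0L, k, k, dimnames = list(true = classes, predicted = classes))
  for (i in seq_along(yTrue))
    cm[yTrue[i], yPred[i]] <- cm[yTrue[i], yPred[i]] + 1L
  cm
}

#' One-vs-rest metrics from a confusion matrix
#'
#' Per class c: TP = cm[c, c], FN = rowSum - TP, FP = colSum - TP,
#' TN = total - TP - FN - FP; then sensitivity TPR = TP/(TP+FN), specificity
#' TNR = TN/(TN+FP), FPR = FP/(TN+FP), FNR = FN/(TP+FN), precision =
#' TP/(TP+FP) and F_beta = (1+beta^2) * precision * TPR /
#' (beta^2 * precision + TPR). The weighted row averages per-class values by
#' true-class support; macro averaging is available. Ratios with a zero
#' denominator are NaN and are excluded from the average (with a warning),
#' the weights being renormalized over the defined classes.
#'
#' @param cm square confusion matrix (true x predicted).
#' @param beta F-score beta (default 1).
#' @param average \code{"weighted"} (default) or \code{"macro"}.
#' @return List with \code{perClass} (data.frame: class, support, TP, FP, TN,
#'   FN and the six metrics), \code{weighted} (named numeric vector),
#'   \code{misclassified} (off-diagonal total) and \code{beta}.
#' @examples
#' cm <- matrix(c(8, 2, 1, 9), 2, 2, byrow = TRUE,
#'              dimnames = list(c("a", "b"), c("a", "b")))
#' metricsFromConfusion(cm)$weighted
#' @export
metricsFromConfusion <- function(cm, beta = 1,
                                 average = c("weighted", "macro")) {
  average <- match.arg(average)
  cm <- as.matrix(cm)
  stopifnot(nrow(cm) == ncol(cm))
  total <- sum(cm)
  if (total <= 0) stop("confusion matrix is empty")
  classes <- rownames(cm)
  if (is.null(classes)) classes <- as.character(seq_len(nrow(cm)))
  tp <- diag(cm)
  fn <- rowSums(cm) - tp
  fp <- colSums(cm) - tp
  tn <- total - tp - fn - fp
  tpr <- tp / (tp + fn)
  tnr <- tn / (tn + fp)
  fpr <- fp / (tn + fp)
  fnr <- fn / (tp + fn)
  precision <- tp / (tp + fp)
  fbeta <- (1 + beta^2) * precision * tpr / (beta^2 * precision + tpr)
  perClass <- data.frame(class = classes, support = rowSums(cm),
                         TP = tp, FP = fp, TN = tn, FN = fn,
                         TPR = tpr, TNR = tnr, FPR = fpr, FNR = fnr,
                         precision = precision, fbeta = fbeta,
                         row.names = NULL)
  support <- rowSums(cm)
  wts <- if (average == "weighted") support / total else
    rep(1 / nrow(cm), nrow(cm))
  avg <- vapply(c("TPR", "TNR", "FPR", "FNR", "precision", "fbeta"),
    function(m) {
      v <- perClass[[m]]
      ok <- is.finite(v)
      if (!all(ok)) {
        warning(sprintf(
          "metric %s undefined (zero denominator) for: %s; excluded from the average",
          m, paste(classes[!ok], collapse = ", ")))
      }
      sum(v[ok] * wts[ok]) / sum(wts[ok])
    }, numeric(1))
  list(perClass = perClass, weighted = avg,
       misclassified = total - sum(tp), beta = beta)
}

#' One-vs-rest ROC AUC from class probability scores
#'
#' For each class, sweeps thresholds over the class score (positives = samples
#' of that class) and integrates TPR against FPR by the trapezoidal rule. The
#' weighted AUC averages per-class values by class support. A class absent
#' from \code{yTrue} gets NaN.
#'
#' @param scores n x k matrix of class scores (rows need not be calibrated,
#'   but typically softmax probabilities; columns named by class).
#' @param yTrue length-n label vector.
#' @param classes class vocabulary (defaults to score column names, else
#'   \code{LEUKOCYTE_CLASSES}).
#' @return List with \code{perClass} (named numeric) and \code{weighted}.
#' @examples
#' s <- rbind(c(0.9, 0.1), c(0.2, 0.8), c(0.7, 0.3), c(0.4, 0.6))
#' colnames(s) <- c("a", "b")
#' rocAuc(s, c("a", "b", "a", "b"))$perClass
#' @export
rocAuc <- function(scores, yTrue, classes = NULL) {
  scores <- as.matrix(scores)
  if (is.null(classes))
    classes <- if (!is.null(colnames(scores))) colnames(scores) else
      LEUKOCYTE_CLASSES[seq_len(ncol(scores))]
  yTrue <- as.character(yTrue)
  stopifnot(length(yTrue) == nrow(scores))
  auc <- vapply(seq_along(classes), function(c) {
    pos <- yTrue == classes[c]
    if (!any(pos) || all(pos)) return(NaN)
    .binaryAuc(scores[, c], pos)
  }, numeric(1))
  names(auc) <- classes
  support <- vapply(classes, function(cl) sum(yTrue == cl), numeric(1))
  ok <- is.finite(auc)
  list(perClass = auc,
       weighted = sum(auc[ok] * support[ok]) / sum(support[ok]))
}

# threshold sweep + trapezoid; ties handled by grouping equal scores
.binaryAuc <- function(s, pos) {
  ord <- order(s, decreasing = TRUE)
  s <- s[ord]; pos <- pos[ord]
  nPos <- sum(pos); nNeg <- sum(!pos)
  grp <- cumsum(!duplicated(s))            # one step per distinct score
  tpCum <- cumsum(pos); fpCum <- cumsum(!pos)
  last <- !duplicated(grp, fromLast = TRUE)
  tpr <- c(0, tpCum[last] / nPos)
  fpr <- c(0, fpCum[last] / nNeg)
  sum(diff(fpr) * (head(tpr, -1) + tpr[-1]) / 2)
}
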