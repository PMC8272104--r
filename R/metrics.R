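#' Rhythm class codes
#'
#' The four rhythm classes, in the fixed order used throughout the package:
#' `N` (normal sinus rhythm), `A` (atrial fibrillation), `O` (other
#' arrhythmia), `P` (too noisy to classify).
#'
#' @return Character vector `c("N", "A", "O", "P")`.
#' @export
ecg_classes <- function() c("N", "A", "O", "P")

#' Confusion matrix for four-class rhythm predictions
#'
#' Tabulates actual against predicted class codes.  Rows are the actual
#' class, columns the predicted class, both in the fixed order
#' N, A, O, P.
#'
#' @param actual character vector of true class codes.
#' @param predicted character vector of predicted class codes, same length.
#' @return An object of class `ecg_confusion`: a 4x4 integer matrix with
#'   dimnames `actual` x `predicted`.
#' @examples
#' cm <- confusion_matrix(c("N", "A", "N"), c("N", "A", "A"))
#' cm["N", "A"]
#' @export
confusion_matrix <- function(actual, predicted) {
  if (length(actual) != length(predicted))
    stop("`actual` and `predicted` must have the same length")
  cls <- ecg_classes()
  bad <- setdiff(unique(c(actual, predicted)), cls)
  if (length(bad))
    stop("invalid class code(s): ", paste(bad, collapse = ", "))
  a <- factor(actual, levels = cls)
  p <- factor(predicted, levels = cls)
  cm <- unclass(table(actual = a, predicted = p))
  storage.mode(cm) <- "integer"
  structure(cm, class = c("ecg_confusion", "matrix"))
}

#' Construct a confusion matrix from raw counts
#'
#' @param counts 4x4 nonnegative matrix of counts, rows = actual,
#'   columns = predicted, in N, A, O, P order.
#' @return An `ecg_confusion` object.
#' @export
as_confusion_matrix <- function(counts) {
  counts <- as.matrix(counts)
  if (!all(dim(counts) == c(4L, 4L)))
    stop("`counts` must be a 4x4 matrix")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("`counts` must hold nonnegative integers")
  storage.mode(counts) <- "integer"
  dimnames(counts) <- list(actual = ecg_classes(), predicted = ecg_classes())
  structure(counts, class = c("ecg_confusion", "matrix"))
}

#' Per-class precision/recall/F1 and the NAO / NAOP macro averages
#'
#' One-vs-rest true positives, false positives and false negatives are
#' read off the confusion matrix per class; then, in percent,
#' \deqn{F_1 = \frac{2 \cdot \mathrm{Precision} \cdot \mathrm{Recall}}
#'   {\mathrm{Precision} + \mathrm{Recall}} \times 100,}
#' with \eqn{\mathrm{Precision} = TP/(TP+FP)} and
#' \eqn{\mathrm{Recall} = TP/(TP+FN)}.  The overall scores are macro
#' averages of the class F1 values over N, A, O (`f1_nao`) and over all
#' four classes (`f1_naop`).  A class with \eqn{TP+FP = 0} or
#' \eqn{TP+FN = 0} scores 0 by convention (0/0 is defined as 0).
#'
#' All arithmetic is carried at full double precision; rounding to two
#' decimals happens only in the print method.
#'
#' @param cm an `ecg_confusion` matrix (see [confusion_matrix()]).
#' @return An object of class `ecg_metrics`: a list with `per_class`
#'   (data frame with tp, fp, fn, precision, recall, f1 in percent),
#'   `f1_nao`, `f1_naop`, and the input `confusion`.
#' @examples
#' cm <- as_confusion_matrix(diag(c(5L, 2L, 2L, 1L)))
#' score_confusion(cm)$f1_naop
#' @export
score_confusion <- function(cm) {
  if (!inherits(cm, "ecg_confusion")) cm <- as_confusion_matrix(cm)
  if (sum(cm) == 0) stop("confusion matrix is all zero")
  cls <- ecg_classes()
  tp <- diag(cm)
  fn <- rowSums(cm) - tp
  fp <- colSums(cm) - tp
  safe_div <- function(num, den) ifelse(den > 0, num / den, 0)
  precision <- safe_div(tp, tp + fp)
  recall <- safe_div(tp, tp + fn)
  f1 <- ifelse(precision + recall > 0,
               2 * precision * recall / (precision + recall), 0)
  per_class <- data.frame(
    class = cls, tp = as.integer(tp), fp = as.integer(fp),
    fn = as.integer(fn),
    precision = 100 * precision, recall = 100 * recall, f1 = 100 * f1,
    row.names = cls
  )
  structure(
    list(
      per_class = per_class,
      f1_nao = mean(per_class$f1[1:3]),
      f1_naop = mean(per_class$f1),
      confusion = cm
    ),
    class = "ecg_metrics"
  )
}

#' @export
print.ecg_metrics <- function(x, digits = 2, ...) {
  cat("Four-class rhythm classification metrics (%)\n\n")
  tab <- x$per_class
  tab$precision <- round(tab$precision, digits)
  tab$recall <- round(tab$recall, digits)
  tab$f1 <- round(tab$f1, digits)
  print(tab, row.names = FALSE)
  cat(sprintf("\nF1 (N+A+O):    %.2f\nF1 (N+A+O+P):  %.2f\n",
              x$f1_nao, x$f1_naop))
  invisible(x)
}

#' @export
print.ecg_confusion <- function(x, ...) {
  cat("Confusion matrix (rows = actual, cols = predicted)\n")
  print(unclass(x))
  invisible(x)
}
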