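# Day-level evaluation of anomaly detection against ground truth:
# sensitivity Tp/(Tp+Fn) and accuracy (Tp+Tn)/N, with abnormal days as the
# positive class.

#' Tally a day-level confusion matrix
#'
#' @param predicted logical vector, TRUE = predicted abnormal.
#' @param truth logical vector of the same length, TRUE = truly abnormal.
#' @return List of class \code{confusion_counts}: \code{Tp}, \code{Tn},
#'   \code{Fp}, \code{Fn}, \code{N}. \code{Tp + Tn + Fp + Fn = N} always.
#' @export
confusion_counts <- function(predicted, truth) {
  if (length(predicted) != length(truth)) {
    stop("predicted and truth must align day by day")
  }
  predicted <- as.logical(predicted); truth <- as.logical(truth)
  structure(list(
    Tp = sum(predicted & truth),
    Tn = sum(!predicted & !truth),
    Fp = sum(predicted & !truth),
    Fn = sum(!predicted & truth),
    N = length(truth)
  ), class = "confusion_counts")
}

#' Sensitivity: fraction of truly abnormal days detected
#' @param c \code{confusion_counts} (or any list with Tp/Fn).
#' @return Tp / (Tp + Fn); error when no positive days exist.
#' @export
sensitivity <- function(c) {
  if (c$Tp + c$Fn == 0) stop("sensitivity undefined: no abnormal days")
  c$Tp / (c$Tp + c$Fn)
}

#' Accuracy: fraction of correctly classified days
#' @param c \code{confusion_counts} (or any list with Tp/Tn and N).
#' @return (Tp + Tn) / N; error when N = 0.
#' @export
accuracy <- function(c) {
  if (c$N == 0) stop("accuracy undefined: no days")
  (c$Tp + c$Tn) / c$N
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("N=%d  Tp=%d Tn=%d Fp=%d Fn=%d  sensitivity=%.2f accuracy=%.2f\n",
              x$N, x$Tp, x$Tn, x$Fp, x$Fn,
              round_half_up(sensitivity(x), 2), round_half_up(accuracy(x), 2)))
  invisible(x)
}
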