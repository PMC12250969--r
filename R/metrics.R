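# Multiclass evaluation metrics from the pooled confusion matrix.

#' Multiclass classification metrics
#'
#' Computes the full metric suite from true and predicted labels:
#' accuracy (trace/total), unweighted macro F1, Cohen's kappa
#' \code{(p_o - p_e)/(1 - p_e)}, macro specificity (one-vs-rest
#' TN/(TN+FP)), macro sensitivity (recall), per-class precision, and the
#' confusion matrix (rows = true, columns = predicted).
#'
#' @param y_true,y_pred Equal-length labels: factors with common levels, or
#'   integers in 1..n_classes.
#' @param classes Class level order; required for integer input when not
#'   all classes occur.
#' @return Object of class \code{"mvbn_metrics"}: list with
#'   \code{accuracy}, \code{macro_f1}, \code{kappa}, \code{specificity},
#'   \code{sensitivity}, \code{per_class_precision}, \code{confusion}.
#' @export
compute_metrics <- function(y_true, y_pred, classes = NULL) {
  if (length(y_true) != length(y_pred) || length(y_true) < 1)
    stop("y_true and y_pred must have equal length >= 1")
  if (is.null(classes)) {
    classes <- if (is.factor(y_true)) levels(y_true)
               else sort(unique(c(as.character(y_true), as.character(y_pred))))
  }
  yt <- factor(y_true, levels = classes)
  yp <- factor(y_pred, levels = classes)
  if (anyNA(yt) || anyNA(yp))
    stop("labels outside the class set: ", paste(classes, collapse = ", "))
  cm <- table(true = yt, predicted = yp)
  cm <- matrix(as.numeric(cm), nrow = length(classes),
               dimnames = list(true = classes, predicted = classes))
  n <- sum(cm)
  tp <- diag(cm)
  rowt <- rowSums(cm)   # true counts per class
  colt <- colSums(cm)   # predicted counts per class

  safe_div <- function(a, b) ifelse(b > 0, a / b, 0)
  precision <- safe_div(tp, colt)
  recall <- safe_div(tp, rowt)
  f1 <- ifelse(precision + recall > 0,
               2 * precision * recall / (precision + recall), 0)
  tn <- n - rowt - colt + tp
  fp <- colt - tp
  specificity <- safe_div(tn, tn + fp)

  p_o <- sum(tp) / n
  p_e <- sum(rowt * colt) / n^2
  kappa <- if (p_e < 1) (p_o - p_e) / (1 - p_e) else if (p_o == 1) 1 else 0

  structure(list(accuracy = p_o,
                 macro_f1 = mean(f1),
                 kappa = kappa,
                 specificity = mean(specificity),
                 sensitivity = mean(recall),
                 per_class_precision = stats::setNames(precision, classes),
                 confusion = cm),
            class = "mvbn_metrics")
}

#' @export
print.mvbn_metrics <- function(x, digits = 3, ...) {
  cat("Accuracy    ", round(x$accuracy, digits), "\n")
  cat("Macro F1    ", round(x$macro_f1, digits), "\n")
  cat("Kappa       ", round(x$kappa, digits), "\n")
  cat("Specificity ", round(x$specificity, digits), "\n")
  cat("Sensitivity ", round(x$sensitivity, digits), "\n")
  cat("Per-class precision:\n")
  print(round(x$per_class_precision, digits))
  cat("Confusion matrix (rows = true):\n")
  print(x$confusion)
  invisible(x)
}

#' Collapse three-stage labels to sleep vs wakefulness
#'
#' Relabels \code{AS} and \code{QS} to \code{SLEEP}; \code{W} is kept. Used
#' for the two-stage task.
#'
#' @param y Factor or character vector of stage labels.
#' @return Factor with levels \code{W}, \code{SLEEP}.
#' @export
stages_to_binary <- function(y) {
  y <- as.character(y)
  y[y %in% c("AS", "QS")] <- "SLEEP"
  factor(y, levels = c("W", "SLEEP"))
}
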