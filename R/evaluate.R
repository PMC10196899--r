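#' Evaluate a classifier on a balanced segment set
#'
#' Computes the confusion matrix, accuracy, precision/recall/F1 (micro and
#' macro averages) and one-vs-rest AUROC: for each class in turn, that class
#' is treated as positive and the remaining classes are pooled into a single
#' negative class. On a perfectly balanced set the micro averages coincide
#' with accuracy.
#'
#' @param model A fitted `bilstm` (or any object with a `predict` method
#'   returning a probability matrix for `type = "prob"`).
#' @param x Segments, array n x channels x w.
#' @param y True labels, length n; every model class must be present.
#' @return An object of class `eval_report`.
#' @export
evaluate_model <- function(model, x, y) {
  probs <- predict(model, x, type = "prob")
  y <- as.character(y)
  classes <- colnames(probs)
  missing_cl <- setdiff(classes, unique(y))
  if (length(missing_cl)) {
    stop_mw("class '%s' absent from the evaluation set", missing_cl[1])
  }
  pred <- classes[max.col(probs)]
  eval_report(pred, y, probs, classes)
}

#' Build an evaluation report from predictions
#'
#' @param pred Predicted labels.
#' @param y True labels.
#' @param probs Optional n x K probability matrix (for AUROC).
#' @param classes Class set; defaults to the union of labels.
#' @return An object of class `eval_report`: `confusion` (rows = truth),
#'   `accuracy`, per-class and averaged precision/recall/F1, per-class and
#'   mean one-vs-rest `auroc`.
#' @export
eval_report <- function(pred, y, probs = NULL, classes = NULL) {
  classes <- classes %||% sort(unique(c(pred, y)))
  pred <- factor(pred, levels = classes)
  y <- factor(y, levels = classes)
  cm <- table(truth = y, predicted = pred)
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  prec <- ifelse(tp + fp == 0, 0, tp / (tp + fp))
  rec <- ifelse(tp + fn == 0, 0, tp / (tp + fn))
  f1 <- ifelse(prec + rec == 0, 0, 2 * prec * rec / (prec + rec))
  micro <- list(
    precision = sum(tp) / (sum(tp) + sum(fp)),
    recall = sum(tp) / (sum(tp) + sum(fn))
  )
  micro$f1 <- 2 * micro$precision * micro$recall /
    (micro$precision + micro$recall)
  auroc <- rep(NA_real_, length(classes))
  names(auroc) <- classes
  if (!is.null(probs)) {
    for (k in seq_along(classes)) {
      resp <- as.integer(y == classes[k])
      if (length(unique(resp)) == 2) {
        auroc[k] <- as.numeric(pROC::auc(
          pROC::roc(resp, probs[, k], quiet = TRUE, direction = "<")))
      }
    }
  }
  structure(list(
    confusion = cm,
    n_per_class = rowSums(cm),
    accuracy = mean(pred == y),
    precision = prec, recall = rec, f1 = f1,
    macro = list(precision = mean(prec), recall = mean(rec), f1 = mean(f1)),
    micro = micro,
    auroc = auroc,
    auroc_mean = if (all(is.na(auroc))) NA_real_ else mean(auroc, na.rm = TRUE)
  ), class = "eval_report")
}

#' @export
print.eval_report <- function(x, digits = 4, ...) {
  cat(sprintf("Accuracy: %.2f%% (%d classes, %d segments)\n",
              100 * x$accuracy, nrow(x$confusion), sum(x$confusion)))
  cat(sprintf("Macro  P/R/F1: %.*f / %.*f / %.*f\n", digits, x$macro$precision,
              digits, x$macro$recall, digits, x$macro$f1))
  cat(sprintf("Micro  P/R/F1: %.*f / %.*f / %.*f\n", digits, x$micro$precision,
              digits, x$micro$recall, digits, x$micro$f1))
  if (!is.na(x$auroc_mean)) {
    cat(sprintf("One-vs-rest AUROC (mean): %.*f\n", digits, x$auroc_mean))
  }
  cat("Confusion matrix (rows = truth):\n")
  print(x$confusion)
  invisible(x)
}

report_to_list <- function(r) {
  list(accuracy = r$accuracy,
       precision_macro = r$macro$precision, recall_macro = r$macro$recall,
       f1_macro = r$macro$f1,
       precision_micro = r$micro$precision, recall_micro = r$micro$recall,
       f1_micro = r$micro$f1,
       auroc = as.list(r$auroc), auroc_mean = r$auroc_mean,
       confusion = unclass(as.matrix(r$confusion)),
       n_per_class = as.list(r$n_per_class))
}
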