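# Evaluation: confusion matrices (rows = true class, columns = predicted),
# per-class precision/recall/F1, accuracy, and ROC/AUC for the binary task.

#' Confusion matrix with true classes as rows
#'
#' @param truth integer vector of true labels.
#' @param predicted integer vector of predicted labels, same length.
#' @param classes the full ordered set of class labels (so absent classes
#'   still get rows/columns).
#' @return integer matrix, `classes x classes`, rows = true.
#' @export
confusion_matrix <- function(truth, predicted, classes = sort(unique(c(truth, predicted)))) {
  stopifnot(length(truth) == length(predicted))
  t_f <- factor(truth, levels = classes)
  p_f <- factor(predicted, levels = classes)
  cm <- table(true = t_f, predicted = p_f)
  matrix(as.integer(cm), nrow = length(classes),
         dimnames = list(true = classes, predicted = classes))
}

#' Row-normalized confusion matrix (percentages)
#'
#' Each row sums to 100 (rows with no items are `NaN`).
#'
#' @param cm a [confusion_matrix()].
#' @return numeric matrix of percentages.
#' @export
confusion_percent <- function(cm) {
  sweep(cm, 1L, rowSums(cm), `/`) * 100
}

#' Per-class precision, recall and F1, plus overall accuracy
#'
#' Precision = TP/(TP+FP), recall = TP/(TP+FN), F1 = their harmonic mean.
#' A class absent from the truth gets `NA` recall/F1; a class never
#' predicted gets `NA` precision — undefined metrics are reported as
#' missing, never as 0.
#'
#' @param cm a [confusion_matrix()].
#' @return list with `per_class` (data.frame `class`, `precision`,
#'   `recall`, `f1`, `support`) and `accuracy`.
#' @export
classification_metrics <- function(cm) {
  tp <- diag(cm)
  support <- rowSums(cm)
  predicted <- colSums(cm)
  precision <- ifelse(predicted > 0, tp / predicted, NA_real_)
  recall <- ifelse(support > 0, tp / support, NA_real_)
  f1 <- ifelse(!is.na(precision) & !is.na(recall) & (precision + recall) > 0,
               2 * precision * recall / (precision + recall), NA_real_)
  list(per_class = data.frame(class = rownames(cm),
                              precision = unname(precision),
                              recall = unname(recall),
                              f1 = unname(f1),
                              support = unname(support)),
       accuracy = sum(tp) / sum(cm))
}

#' ROC curve of a binary scorer
#'
#' Sweeps every distinct score as a threshold (predict positive when
#' `score >= threshold`); ties are grouped so the curve is a step function
#' through `(0,0)` and `(1,1)`.
#'
#' @param truth 0/1 vector.
#' @param scores numeric scores, higher = more positive.
#' @return data.frame with columns `threshold`, `fpr`, `tpr`.
#' @export
roc_curve <- function(truth, scores) {
  stopifnot(length(truth) == length(scores),
            all(truth %in% c(0L, 1L)))
  n_pos <- sum(truth == 1L)
  n_neg <- sum(truth == 0L)
  if (n_pos == 0L || n_neg == 0L) {
    stop("ROC needs both classes present", call. = FALSE)
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- truth[ord]
  tp <- cumsum(y == 1L)
  fp <- cumsum(y == 0L)
  last_of_tie <- c(s[-1] != s[-length(s)], TRUE)
  data.frame(threshold = c(Inf, s[last_of_tie]),
             fpr = c(0, fp[last_of_tie] / n_neg),
             tpr = c(0, tp[last_of_tie] / n_pos))
}

#' Area under the ROC curve (trapezoidal rule)
#'
#' Invariant under strictly monotone transforms of the scores.
#'
#' @inheritParams roc_curve
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(truth, scores) {
  rc <- roc_curve(truth, scores)
  sum(diff(rc$fpr) * (utils::head(rc$tpr, -1) + utils::tail(rc$tpr, -1)) / 2)
}

#' Evaluate a trained MLP on a test set
#'
#' Produces the full quality report: confusion matrix (rows = true class),
#' row percentages, per-class precision/recall/F1, overall accuracy, and —
#' for the binary head — the ROC curve over the sigmoid score with its
#' trapezoidal AUC. The decision rule is argmax (multiclass) or
#' score > 0.5 (binary).
#'
#' @param model a trained [mlp_model][build_mlp()].
#' @param test an [st_dataset()] (e.g. `split$test`), non-empty.
#' @param history optional training history to embed in the report.
#' @return an object of class `eval_report`.
#' @export
evaluate_mlp <- function(model, test, history = NULL) {
  stopifnot(inherits(model, "mlp_model"), inherits(test, "st_dataset"))
  if (nrow(test$features) == 0L) stop("empty test set", call. = FALSE)
  mode <- model$config$mode
  probs <- predict_mlp(model, test$features, type = "prob")
  pred <- .pred_classes(probs, mode)
  truth <- as.integer(test$meta$label)
  classes <- seq_len(max(model$config$output_dim, 2L)) - 1L
  cm <- confusion_matrix(truth, pred, classes = classes)
  metrics <- classification_metrics(cm)
  report <- list(mode = mode,
                 confusion = cm,
                 confusion_percent = confusion_percent(cm),
                 per_class = metrics$per_class,
                 accuracy = metrics$accuracy,
                 n_test = length(truth),
                 history = history)
  if (mode == "binary") {
    report$roc <- roc_curve(truth, probs[, 1L])
    report$auc <- roc_auc(truth, probs[, 1L])
  }
  structure(report, class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("MLP evaluation (%s), %d test vectors\n", x$mode, x$n_test))
  cat(sprintf("accuracy: %.3f", x$accuracy))
  if (!is.null(x$auc)) cat(sprintf("   AUC: %.3f", x$auc))
  cat("\n\nconfusion matrix (rows = true class, %):\n")
  print(round(x$confusion_percent, 1))
  cat("\nper-class metrics:\n")
  pc <- x$per_class
  pc[, c("precision", "recall", "f1")] <-
    round(pc[, c("precision", "recall", "f1")], 3)
  print(pc, row.names = FALSE)
  invisible(x)
}

#' Export an evaluation report as JSON
#'
#' @param report an [evaluate_mlp()] report.
#' @param path JSON path.
#' @return `path`, invisibly.
#' @export
write_eval_report <- function(report, path) {
  stopifnot(inherits(report, "eval_report"))
  out <- list(mode = report$mode,
              accuracy = report$accuracy,
              n_test = report$n_test,
              confusion = as.data.frame(as.table(report$confusion)),
              per_class = report$per_class)
  if (!is.null(report$auc)) {
    out$auc <- report$auc
    out$roc <- report$roc
  }
  if (!is.null(report$history)) out$history <- report$history
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}
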