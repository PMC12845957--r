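# Detection metrics: confusion matrix, per-class precision/recall/F1 with
# macro and support-weighted averages, named class-conditional error rates,
# Matthews correlation, ROC and precision-recall curves.
#
# Error rates are reported by class name (error_rate_humpback = fraction of
# true humpback windows misclassified; error_rate_nocall likewise) rather
# than as FNR/FPR, whose orientation depends on an implicit positive class.

#' Confusion matrix from true and predicted labels
#'
#' @param true_labels,predicted_labels character vectors over the binary
#'   alphabet (`"humpback"`, `"no_call"`), equal length.
#' @param classes class alphabet, first element taken as the positive class.
#' @param positive_class class used to orient positive-class metrics.
#' @return 2x2 integer matrix of class `confusion_matrix`, rows = true class,
#'   columns = predicted class.
#' @export
confusion <- function(true_labels, predicted_labels, classes = whale_classes(),
                      positive_class = classes[1L]) {
  if (length(true_labels) != length(predicted_labels)) {
    stop("true and predicted label vectors differ in length")
  }
  bad <- setdiff(unique(c(true_labels, predicted_labels)), classes)
  if (length(bad)) {
    stop(sprintf("unknown labels: %s", paste(bad, collapse = ", ")))
  }
  tt <- table(factor(true_labels, levels = classes),
              factor(predicted_labels, levels = classes))
  cm <- matrix(as.integer(tt), 2L, 2L, dimnames = list(true = classes,
                                                       predicted = classes))
  structure(cm, positive_class = positive_class,
            class = c("confusion_matrix", "matrix"))
}

#' Assemble a confusion matrix directly from counts
#'
#' Row order is the class alphabet; `counts[i, j]` is the number of windows of
#' true class i predicted as class j.
#' @param counts 2x2 numeric matrix of counts.
#' @inheritParams confusion
#' @export
confusion_from_counts <- function(counts, classes = whale_classes(),
                                  positive_class = classes[1L]) {
  counts <- matrix(as.integer(counts), 2L, 2L,
                   dimnames = list(true = classes, predicted = classes))
  if (any(counts < 0)) stop("counts must be non-negative")
  structure(counts, positive_class = positive_class,
            class = c("confusion_matrix", "matrix"))
}

#' Full evaluation report from a confusion matrix
#'
#' Computes accuracy, per-class precision/recall/F1/support, macro (unweighted
#' mean) and support-weighted averages, both class-conditional error rates,
#' and the Matthews correlation coefficient. Zero-denominator metrics return
#' 0 and set the `degenerate` flag. Mean cross-entropy is included when
#' per-window losses are supplied.
#'
#' @param cm a [confusion()] matrix.
#' @param losses optional numeric vector of per-window cross-entropies.
#' @return list of class `eval_report`.
#' @export
summarize <- function(cm, losses = NULL) {
  counts <- unclass(cm)
  total <- sum(counts)
  if (total == 0) stop("empty confusion matrix")
  classes <- rownames(counts)
  degenerate <- FALSE
  safe_div <- function(num, den) {
    if (den == 0) {
      degenerate <<- TRUE
      0
    } else {
      num / den
    }
  }
  per_class <- lapply(seq_along(classes), function(i) {
    tp <- counts[i, i]
    support <- sum(counts[i, ])
    precision <- safe_div(tp, sum(counts[, i]))
    recall <- safe_div(tp, support)
    f1 <- if (precision + recall == 0) {
      degenerate <<- TRUE
      0
    } else {
      2 * precision * recall / (precision + recall)
    }
    list(class = classes[i], precision = precision, recall = recall, f1 = f1,
         support = support)
  })
  names(per_class) <- classes
  prec <- vapply(per_class, `[[`, 0, "precision")
  rec <- vapply(per_class, `[[`, 0, "recall")
  f1 <- vapply(per_class, `[[`, 0, "f1")
  supp <- vapply(per_class, `[[`, 0, "support")
  err <- vapply(seq_along(classes), function(i) {
    safe_div(sum(counts[i, ]) - counts[i, i], sum(counts[i, ]))
  }, 0)
  names(err) <- paste0("error_rate_", sub("no_call", "nocall", classes))
  mcc_val <- mcc_from_counts(counts)
  if (is.na(mcc_val)) {
    degenerate <- TRUE
    mcc_val <- 0
  }
  structure(list(
    confusion = cm,
    accuracy = sum(diag(counts)) / total,
    loss = if (is.null(losses)) NA_real_ else mean(losses),
    per_class = per_class,
    macro = c(precision = mean(prec), recall = mean(rec), f1 = mean(f1)),
    weighted = c(precision = sum(prec * supp) / total,
                 recall = sum(rec * supp) / total,
                 f1 = sum(f1 * supp) / total),
    error_rates = err,
    mcc = mcc_val,
    total = total,
    degenerate = degenerate,
    positive_class = attr(cm, "positive_class")
  ), class = "eval_report")
}

# Matthews correlation from 2x2 counts; NA when a marginal is empty.
mcc_from_counts <- function(counts) {
  tp <- as.numeric(counts[1L, 1L])
  fn <- as.numeric(counts[1L, 2L])
  fp <- as.numeric(counts[2L, 1L])
  tn <- as.numeric(counts[2L, 2L])
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (den == 0) return(NA_real_)
  (tp * tn - fp * fn) / sqrt(den)
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("Evaluation over %d windows\n", x$total))
  cat(sprintf("  accuracy: %.2f%%", 100 * x$accuracy))
  if (!is.na(x$loss)) cat(sprintf("   loss: %.4f", x$loss))
  cat(sprintf("   MCC: %.2f\n", x$mcc))
  cat("  class            prec  recall  F1  support\n")
  for (pc in x$per_class) {
    cat(sprintf("  %-15s %4.0f%% %5.0f%% %4.0f%% %7d\n", pc$class,
                100 * pc$precision, 100 * pc$recall, 100 * pc$f1, pc$support))
  }
  cat(sprintf("  macro avg       %4.0f%% %5.0f%% %4.0f%%\n",
              100 * x$macro["precision"], 100 * x$macro["recall"],
              100 * x$macro["f1"]))
  cat(sprintf("  weighted avg    %4.0f%% %5.0f%% %4.0f%%\n",
              100 * x$weighted["precision"], 100 * x$weighted["recall"],
              100 * x$weighted["f1"]))
  for (nm in names(x$error_rates)) {
    cat(sprintf("  %s: %.2f%%\n", nm, 100 * x$error_rates[nm]))
  }
  if (x$degenerate) cat("  note: degenerate zero-denominator metrics set to 0\n")
  invisible(x)
}

#' ROC and precision-recall curves with areas
#'
#' ROC points are computed at every distinct score threshold (predict positive
#' when score >= threshold) and the area is the trapezoidal integral, which
#' equals the Mann-Whitney pairwise concordance probability. The PR curve uses
#' the same thresholds; average precision is the step-function integral
#' `sum((R_i - R_{i-1}) * P_i)` over decreasing thresholds.
#'
#' @param scores numeric vector in `[0, 1]`: probability of the positive class.
#' @param true_labels character vector over the class alphabet.
#' @param positive_class label counted as positive.
#' @return list of class `roc_pr`: `roc` (data.frame fpr/tpr), `auc`,
#'   `pr` (data.frame recall/precision), `average_precision`.
#' @export
roc_pr <- function(scores, true_labels, positive_class = whale_classes()[1L]) {
  if (length(scores) != length(true_labels)) stop("length mismatch")
  if (any(scores < 0 | scores > 1)) stop("scores must lie in [0, 1]")
  y <- true_labels == positive_class
  if (all(y)) stop(sprintf("only class '%s' present in truth", positive_class))
  if (!any(y)) stop(sprintf("class '%s' absent from truth", positive_class))
  np <- sum(y)
  nn <- sum(!y)
  ord <- order(scores, decreasing = TRUE)
  ys <- y[ord]
  ss <- scores[ord]
  tp <- cumsum(ys)
  fp <- cumsum(!ys)
  last <- c(diff(ss) != 0, TRUE) # keep one point per distinct threshold
  tpr <- c(0, tp[last] / np)
  fpr <- c(0, fp[last] / nn)
  auc <- sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
  precision <- tp[last] / (tp[last] + fp[last])
  recall <- tp[last] / np
  ap <- sum(diff(c(0, recall)) * precision)
  structure(list(
    roc = data.frame(fpr = fpr, tpr = tpr),
    auc = auc,
    pr = data.frame(recall = recall, precision = precision),
    average_precision = ap,
    thresholds = ss[last]
  ), class = "roc_pr")
}

#' @export
print.roc_pr <- function(x, ...) {
  cat(sprintf("ROC AUC: %.4f   average precision: %.4f   (%d thresholds)\n",
              x$auc, x$average_precision, length(x$thresholds)))
  invisible(x)
}

#' Evaluate predictions end to end
#'
#' @param true_labels character truth vector.
#' @param p_positive probability of the positive (humpback) class per window.
#' @param losses optional per-window cross-entropies.
#' @param classes class alphabet.
#' @return `eval_report` with an additional `curves` element ([roc_pr()]).
#' @export
evaluate_predictions <- function(true_labels, p_positive, losses = NULL,
                                 classes = whale_classes()) {
  predicted <- ifelse(p_positive >= 0.5, classes[1L], classes[2L])
  rep <- summarize(confusion(true_labels, predicted, classes), losses)
  rep$curves <- tryCatch(roc_pr(p_positive, true_labels, classes[1L]),
                         error = function(e) NULL)
  rep
}

#' Write an evaluation report as JSON
#' @param report an `eval_report`.
#' @param path output file.
#' @export
write_report_json <- function(report, path) {
  x <- list(
    accuracy = report$accuracy,
    loss = report$loss,
    mcc = report$mcc,
    error_rates = as.list(report$error_rates),
    macro = as.list(report$macro),
    weighted = as.list(report$weighted),
    per_class = lapply(report$per_class, function(p) p[c("precision", "recall", "f1", "support")]),
    confusion = unclass(report$confusion),
    auc = if (!is.null(report$curves)) report$curves$auc else NULL,
    average_precision = if (!is.null(report$curves)) report$curves$average_precision else NULL
  )
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
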