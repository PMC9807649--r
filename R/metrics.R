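# Binary-classification evaluation with the cystic state (1) as the
# positive class: confusion counts and the derived accuracy / sensitivity /
# specificity, ROC/AUC, and DeLong's test for paired ROC curves.

#' Confusion-matrix metrics
#'
#' Counts TP/TN/FP/FN with state 1 (cystic) as positive and derives
#' `accuracy = (TP+TN)/(TP+TN+FP+FN)`, `sensitivity = TP/(TP+FN)` and
#' `specificity = TN/(TN+FP)`. A ratio with a zero denominator is reported
#' as `NA` and listed in `$undefined` rather than silently coerced to 0.
#'
#' @param pred Predicted states over \{1, 2\}.
#' @param truth True states over \{1, 2\}, same length.
#' @return An object of class `eval_report`: list with integer counts `TP`,
#'   `TN`, `FP`, `FN`, proportions `accuracy`, `sensitivity`,
#'   `specificity`, and `undefined` (character vector of flagged metrics).
#' @export
confusion_metrics <- function(pred, truth) {
  pred <- check_labels(pred); truth <- check_labels(truth)
  if (length(pred) != length(truth))
    stopf("pred (%d) and truth (%d) must have equal length",
          length(pred), length(truth))
  TP <- sum(pred == 1L & truth == 1L)
  TN <- sum(pred == 2L & truth == 2L)
  FP <- sum(pred == 1L & truth == 2L)
  FN <- sum(pred == 2L & truth == 1L)
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  out <- list(TP = TP, TN = TN, FP = FP, FN = FN,
              accuracy = ratio(TP + TN, TP + TN + FP + FN),
              sensitivity = ratio(TP, TP + FN),
              specificity = ratio(TN, TN + FP))
  out$undefined <- names(which(vapply(
    out[c("accuracy", "sensitivity", "specificity")], is.na, TRUE)))
  structure(out, class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report: TP=%d TN=%d FP=%d FN=%d | acc=%.3f sens=%.3f spec=%.3f>\n",
              x$TP, x$TN, x$FP, x$FN, x$accuracy, x$sensitivity, x$specificity))
  if (length(x$undefined))
    cat("  undefined (zero denominator):", paste(x$undefined, collapse = ", "), "\n")
  invisible(x)
}

as_roc_truth <- function(truth) {
  truth <- check_labels(truth)
  if (length(unique(truth)) < 2L)
    stopf("ROC requires both classes present in truth")
  truth
}

#' ROC curve and AUC
#'
#' Sweeps thresholds over the unique score values (scores oriented so larger
#' means more cystic) and returns the ROC points plus the trapezoidal AUC,
#' which equals the rank statistic P(random positive outscores a random
#' negative), ties counted 1/2.
#'
#' @param scores Numeric scores, one per case.
#' @param truth True states over \{1, 2\} (1 = cystic = positive); both
#'   classes must be present.
#' @return List with `roc` (data.frame of `fpr`, `tpr` points) and `auc`.
#' @export
roc_auc <- function(scores, truth) {
  truth <- as_roc_truth(truth)
  if (length(scores) != length(truth))
    stopf("scores and truth must have equal length")
  r <- pROC::roc(response = truth, predictor = as.numeric(scores),
                 levels = c("2", "1"), direction = "<", quiet = TRUE)
  pts <- data.frame(fpr = 1 - r$specificities, tpr = r$sensitivities)
  pts <- pts[order(pts$fpr, pts$tpr), , drop = FALSE]
  rownames(pts) <- NULL
  list(roc = pts, auc = as.numeric(r$auc))
}

#' DeLong's test for two paired ROC curves
#'
#' Compares the AUCs of two scoring methods evaluated on the same cases via
#' DeLong's placement-value (structural components) covariance estimate and
#' a two-sided normal p-value for `auc_a - auc_b`. When the two score
#' vectors are identical the difference and its variance are both zero; this
#' degenerate case is reported as `z = 0, p = 1`.
#'
#' @param scores_a,scores_b Paired scores from the two methods.
#' @param truth True states over \{1, 2\}, both classes present.
#' @return List with `auc_a`, `auc_b`, `z`, `p_value`.
#' @export
delong_test <- function(scores_a, scores_b, truth) {
  truth <- as_roc_truth(truth)
  if (length(scores_a) != length(truth) || length(scores_b) != length(truth))
    stopf("scores and truth must have equal length")
  ra <- pROC::roc(response = truth, predictor = as.numeric(scores_a),
                  levels = c("2", "1"), direction = "<", quiet = TRUE)
  rb <- pROC::roc(response = truth, predictor = as.numeric(scores_b),
                  levels = c("2", "1"), direction = "<", quiet = TRUE)
  auc_a <- as.numeric(ra$auc); auc_b <- as.numeric(rb$auc)
  if (isTRUE(all.equal(as.numeric(scores_a), as.numeric(scores_b))))
    return(list(auc_a = auc_a, auc_b = auc_b, z = 0, p_value = 1))
  tst <- suppressWarnings(
    pROC::roc.test(ra, rb, method = "delong", paired = TRUE))
  z <- as.numeric(tst$statistic)
  p <- as.numeric(tst$p.value)
  if (!is.finite(z)) {   # zero-variance difference with equal AUCs
    z <- 0; p <- 1
  }
  list(auc_a = auc_a, auc_b = auc_b, z = z, p_value = p)
}
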