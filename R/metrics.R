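#' Binary confusion matrix
#'
#' Counts with OSCC (or the supplied `positive` label) as the positive
#' class: TP and FN partition the true positives' predictions, TN and FP
#' the true negatives'.
#'
#' @param y_true,y_pred equal-length vectors over the same two labels.
#' @param positive the positive-class label (default `"OSCC"`, falling
#'   back to the second factor level if absent).
#' @return a `confusion_matrix`: list with integers `TP`, `FN`, `TN`,
#'   `FP`.
#' @export
confusion <- function(y_true, y_pred, positive = "OSCC") {
  if (length(y_true) != length(y_pred)) {
    stop("y_true and y_pred must have equal length", call. = FALSE)
  }
  y_true <- as.character(y_true)
  y_pred <- as.character(y_pred)
  labs <- sort(unique(c(y_true, y_pred)))
  if (length(labs) > 2) {
    stop("labels must be binary, got: ", paste(labs, collapse = ", "),
         call. = FALSE)
  }
  if (!positive %in% labs) positive <- labs[length(labs)]
  tp <- sum(y_true == positive & y_pred == positive)
  fn <- sum(y_true == positive & y_pred != positive)
  tn <- sum(y_true != positive & y_pred != positive)
  fp <- sum(y_true != positive & y_pred == positive)
  confusion_matrix(tp, fn, tn, fp)
}

#' @rdname confusion
#' @param TP,FN,TN,FP non-negative counts (total must be positive).
#' @export
confusion_matrix <- function(TP, FN, TN, FP) {
  counts <- c(TP = TP, FN = FN, TN = TN, FP = FP)
  if (any(counts < 0) || sum(counts) == 0) {
    stop("counts must be non-negative with positive total", call. = FALSE)
  }
  structure(as.list(counts), class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("<confusion_matrix> TP=%d FN=%d TN=%d FP=%d\n",
              x$TP, x$FN, x$TN, x$FP))
  invisible(x)
}

#' Percent-scale performance metrics from a confusion matrix
#'
#' The six standard measures on the percent scale, rounded half away
#' from zero to 4 decimals (the convention of the published tables):
#' accuracy `AC = (TP+TN)/total`, misclassification `MC = 100 - AC`
#' (exact by construction), precision `PR = TP/(TP+FP)`, sensitivity
#' `SE = TP/(TP+FN)`, specificity `SP = TN/(TN+FP)` and F1-score
#' `FS = 2TP/(2TP+FN+FP)`, each times 100. A metric whose denominator is
#' zero is reported as `NA` and flagged in `undefined` — never silently
#' coerced to 0 or 100.
#'
#' @param cm a [confusion_matrix()].
#' @return a `metric_report`: list with `AC`, `MC`, `PR`, `SE`, `SP`,
#'   `FS` and a named logical `undefined`.
#' @export
cm_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  total <- cm$TP + cm$FN + cm$TN + cm$FP
  pct <- function(num, den) {
    if (den == 0) NA_real_ else round_half_up(num / den * 100, 4)
  }
  ac <- pct(cm$TP + cm$TN, total)
  out <- list(AC = ac,
              MC = 100 - ac,
              PR = pct(cm$TP, cm$TP + cm$FP),
              SE = pct(cm$TP, cm$TP + cm$FN),
              SP = pct(cm$TN, cm$TN + cm$FP),
              FS = pct(2 * cm$TP, 2 * cm$TP + cm$FN + cm$FP))
  out$undefined <- vapply(out[c("AC", "MC", "PR", "SE", "SP", "FS")],
                          is.na, logical(1))
  structure(out, class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  v <- unlist(x[c("AC", "MC", "PR", "SE", "SP", "FS")])
  cat("<metric_report>",
      paste(sprintf("%s=%.4f", names(v), v), collapse = " "), "\n")
  invisible(x)
}

#' Five-metric tuple for ensemble weighting
#'
#' @param report a [cm_metrics()] result.
#' @return numeric `(AC, PR, SE, SP, FS)` on the percent scale.
#' @export
metric_tuple <- function(report) {
  unlist(report[c("AC", "PR", "SE", "SP", "FS")])
}

#' ROC curve and area under the curve
#'
#' Stepwise ROC from continuous scores: thresholds sweep the distinct
#' score values from high to low, tied scores move as one group (so the
#' curve takes a diagonal step through ties), and the area is computed
#' by the trapezoid rule — equal to the pairwise concordance probability
#' with ties counted 1/2. Constant scores yield the chance diagonal
#' (area 0.5) with a warning.
#'
#' @param scores numeric scores, larger meaning more positive.
#' @param labels binary labels aligned with `scores`.
#' @param positive positive-class label (default `"OSCC"`, falling back
#'   to the second sorted label).
#' @return list with `points` (`data.frame` of `threshold`, `fpr`,
#'   `tpr`) and `auc`.
#' @export
roc_curve <- function(scores, labels, positive = "OSCC") {
  labels <- as.character(labels)
  labs <- sort(unique(labels))
  if (length(labs) != 2) {
    stop("both classes must be present", call. = FALSE)
  }
  if (!positive %in% labs) positive <- labs[2]
  pos <- labels == positive
  n_pos <- sum(pos); n_neg <- sum(!pos)
  if (length(unique(scores)) == 1) {
    warning("constant scores: ROC is the chance diagonal (AUC 0.5)")
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; p <- pos[ord]
  grp <- cumsum(c(TRUE, diff(s) != 0))
  tp <- cumsum(p); fp <- cumsum(!p)
  last <- !duplicated(grp, fromLast = TRUE)
  pts <- data.frame(threshold = c(Inf, s[last]),
                    fpr = c(0, fp[last] / n_neg),
                    tpr = c(0, tp[last] / n_pos))
  auc <- sum(diff(pts$fpr) * (utils::head(pts$tpr, -1) +
                                utils::tail(pts$tpr, -1)) / 2)
  list(points = pts, auc = auc)
}
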