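#' Confusion counts from hard predictions
#'
#' @param labels true class labels.
#' @param predicted predicted class labels.
#' @param positive label of the positive class (default "recurrence").
#' @return Named integer vector (tp, fp, tn, fn).
#' @export
confusion_from_predictions <- function(labels, predicted, positive = "recurrence") {
  labels <- as.character(labels)
  predicted <- as.character(predicted)
  c(tp = sum(predicted == positive & labels == positive),
    fp = sum(predicted == positive & labels != positive),
    tn = sum(predicted != positive & labels != positive),
    fn = sum(predicted != positive & labels == positive))
}

#' Confusion-derived diagnostic metrics
#'
#' Sensitivity TP/(TP+FN), specificity TN/(TN+FP), positive and negative
#' predictive values, and accuracy. A metric with an empty margin is
#' reported as \code{NA} (undefined), never as 0, and is listed in the
#' \code{undefined} attribute.
#'
#' @param counts named vector with tp, fp, tn, fn.
#' @return Named list of the five metrics (fractions in [0, 1]).
#' @export
confusion_metrics <- function(counts) {
  tp <- counts[["tp"]]; fp <- counts[["fp"]]
  tn <- counts[["tn"]]; fn <- counts[["fn"]]
  stop_if(any(c(tp, fp, tn, fn) < 0), "confusion counts must be non-negative")
  rat <- function(num, den) if (den > 0) num / den else NA_real_
  out <- list(sensitivity = rat(tp, tp + fn),
              specificity = rat(tn, tn + fp),
              ppv = rat(tp, tp + fp),
              npv = rat(tn, tn + fn),
              accuracy = rat(tp + tn, tp + fp + tn + fn))
  undef <- names(out)[vapply(out, is.na, logical(1))]
  if (length(undef)) attr(out, "undefined") <- undef
  out
}

#' ROC curve, AUC and Youden-optimal cutoff
#'
#' AUC is the rank statistic P(score_pos > score_neg) + 0.5 P(tie). The
#' curve sweeps all distinct scores as cutoffs with the decision rule
#' score >= cutoff => positive; the optimal cutoff maximizes Youden's
#' J = sensitivity + specificity - 1, ties resolved toward the lower cutoff.
#'
#' @param scores per-lesion continuous scores (higher = more positive-like).
#' @param labels class labels.
#' @param positive positive-class label (default "recurrence").
#' @return An object of class \code{roc_result}: thresholds, fpr, tpr
#'   (anchored at (0,0) and (1,1)), \code{auc}, \code{cutoff},
#'   \code{youden}.
#' @export
roc_auc <- function(scores, labels, positive = "recurrence") {
  labels <- as.character(labels)
  is_pos <- labels == positive
  n1 <- sum(is_pos)
  n0 <- sum(!is_pos)
  stop_if(n1 == 0 || n0 == 0, "both classes must be present for ROC analysis")
  r <- rank(scores)
  auc <- (sum(r[is_pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  thr <- sort(unique(scores))
  sens <- vapply(thr, function(t) sum(is_pos & scores >= t) / n1, numeric(1))
  spec <- vapply(thr, function(t) sum(!is_pos & scores < t) / n0, numeric(1))
  j <- sens + spec - 1
  best <- which(j == max(j))[1] # thresholds ascend, so the first max is the lowest cutoff
  fpr <- c(1 - spec, 0)
  tpr <- c(sens, 0)
  o <- order(fpr, tpr)
  structure(list(thresholds = c(thr, Inf)[o], fpr = fpr[o], tpr = tpr[o],
                 auc = auc, cutoff = thr[best], youden = j[best]),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC %.4f; Youden-optimal cutoff %.4g (J = %.3f)\n",
              x$auc, x$cutoff, x$youden))
  invisible(x)
}

#' Mann-Whitney U test
#'
#' Two-sided rank-sum test: exact by enumeration when the combined sample
#' size is at most 12 and tie-free, otherwise the normal approximation with
#' tie and continuity corrections.
#'
#' @param x,y numeric samples for the two groups.
#' @return List with \code{u} (the U statistic of \code{x}) and \code{p}.
#' @export
mann_whitney_u <- function(x, y) {
  stop_if(length(x) == 0 || length(y) == 0, "both groups must be nonempty")
  ties <- anyDuplicated(c(x, y)) > 0
  use_exact <- (length(x) + length(y)) <= 12 && !ties
  ht <- suppressWarnings(
    stats::wilcox.test(x, y, exact = use_exact, correct = TRUE)
  )
  list(u = unname(ht$statistic), p = ht$p.value)
}

#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks with a t-distribution approximation for
#' the p-value. Constant input has no defined rank correlation and is
#' rejected.
#'
#' @param x,y numeric vectors of equal length (n >= 3).
#' @return List with \code{rho} and \code{p}.
#' @export
spearman_corr <- function(x, y) {
  stop_if(length(x) != length(y) || length(x) < 3,
          "spearman_corr needs two equal-length vectors with n >= 3")
  stop_if(stats::sd(x) == 0 || stats::sd(y) == 0,
          "rank correlation is undefined for constant input")
  ht <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = FALSE, continuity = FALSE)
  )
  list(rho = unname(ht$estimate), p = max(ht$p.value, .Machine$double.xmin))
}

#' Per-feature group comparison
#'
#' For every feature column: Mann-Whitney U test between the two classes,
#' class medians with interquartile ranges (linear-interpolation quartiles),
#' and a significance flag at \code{alpha} (raw p-values by default; a
#' Benjamini-Hochberg option is available).
#'
#' @param features numeric matrix or data frame (rows = lesions).
#' @param labels class labels (two classes).
#' @param positive positive-class label.
#' @param alpha significance level (default 0.05).
#' @param p_adjust \code{"none"} (default) or \code{"BH"}.
#' @return Data frame with one row per feature.
#' @export
compare_groups <- function(features, labels, positive = "recurrence",
                           alpha = 0.05, p_adjust = c("none", "BH")) {
  p_adjust <- match.arg(p_adjust)
  features <- as.matrix(features)
  labels <- as.character(labels)
  classes <- unique(labels)
  stop_if(length(classes) != 2, "exactly two classes required")
  negative <- setdiff(classes, positive)
  rows <- lapply(colnames(features), function(f) {
    xp <- features[labels == positive, f]
    xn <- features[labels == negative, f]
    mw <- mann_whitney_u(xp, xn)
    qp <- quartiles(xp)
    qn <- quartiles(xn)
    data.frame(feature = f,
               median_pos = qp[2], q1_pos = qp[1], q3_pos = qp[3],
               median_neg = qn[2], q1_neg = qn[1], q3_neg = qn[3],
               u = mw$u, p = mw$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$p, method = if (p_adjust == "BH") "BH" else "none")
  out$significant <- out$p_adj < alpha
  rownames(out) <- NULL
  out
}
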