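#' ROC analysis with the Youden-optimal cutoff
#'
#' Computes the area under the ROC curve by the rank (pairwise-concordance)
#' formulation, with half credit for ties, and the operating point that
#' maximizes Youden's J = sensitivity + specificity - 1.
#'
#' The direction is auto-detected: if higher scores in the positive class
#' give AUC < 0.5, the orientation is flipped (so the reported AUC is always
#' >= 0.5 on the training labels) and recorded in `direction`
#' (`"higher"` = positives have higher scores, `"lower"` = positives have
#' lower scores). Cutoff candidates are midpoints between adjacent distinct
#' scores; ties in J are broken toward higher sensitivity, then toward the
#' lower cutoff. Sensitivity, specificity, predictive values and accuracy are
#' reported in percent at the chosen cutoff.
#'
#' @param scores numeric marker values.
#' @param labels binary outcome (0/1, logical, or two-level factor); both
#'   classes must be present.
#' @param direction `"auto"` (default), `"higher"` or `"lower"`.
#' @return A `roc_result` with `auc`, `direction`, `cutoff`, `sensitivity`,
#'   `specificity`, `ppv`, `npv`, `accuracy` (all %), `youden_j`,
#'   `n_pos`, `n_neg`, and the full `curve` (data.frame of all candidate
#'   cutoffs with sens/spec).
#' @examples
#' roc_with_youden(c(1, 2, 3, 10, 11, 12), c(0, 0, 0, 1, 1, 1))
#' @export
roc_with_youden <- function(scores, labels, direction = c("auto", "higher", "lower")) {
  direction <- match.arg(direction)
  if (length(scores) != length(labels))
    stop("scores and labels must have equal length")
  if (any(!is.finite(scores))) stop("scores must be finite")
  y <- as_binary_labels(labels)
  n_pos <- sum(y == 1L); n_neg <- sum(y == 0L)
  if (n_pos == 0L || n_neg == 0L)
    stop("both classes must be present in labels")

  auc_higher <- auc_rank(scores, y)
  if (direction == "auto")
    direction <- if (auc_higher >= 0.5) "higher" else "lower"
  auc <- if (direction == "higher") auc_higher else 1 - auc_higher
  s <- if (direction == "higher") scores else -scores

  # candidate cutoffs: midpoints between adjacent distinct (oriented) scores,
  # plus sentinels classifying all or none as positive
  us <- sort(unique(s))
  cand <- if (length(us) > 1) (us[-1] + us[-length(us)]) / 2 else numeric(0)
  cand <- c(min(us) - 1, cand, max(us) + 1)

  sens <- vapply(cand, function(c) sum(s > c & y == 1L) / n_pos, numeric(1))
  spec <- vapply(cand, function(c) sum(s <= c & y == 0L) / n_neg, numeric(1))
  j <- sens + spec - 1
  best <- order(-j, -sens, cand)[1]
  cutoff_oriented <- cand[best]
  pred_pos <- s > cutoff_oriented
  tp <- sum(pred_pos & y == 1L); fp <- sum(pred_pos & y == 0L)
  fn <- sum(!pred_pos & y == 1L); tn <- sum(!pred_pos & y == 0L)

  structure(list(
    auc = auc,
    direction = direction,
    cutoff = if (direction == "higher") cutoff_oriented else -cutoff_oriented,
    sensitivity = 100 * tp / (tp + fn),
    specificity = 100 * tn / (tn + fp),
    ppv = if (tp + fp > 0) 100 * tp / (tp + fp) else NA_real_,
    npv = if (tn + fn > 0) 100 * tn / (tn + fn) else NA_real_,
    accuracy = 100 * (tp + tn) / length(y),
    youden_j = j[best],
    n_pos = n_pos, n_neg = n_neg,
    curve = data.frame(cutoff = if (direction == "higher") cand else -cand,
                       sensitivity = 100 * sens, specificity = 100 * spec)
  ), class = "roc_result")
}

# AUC by midranks: P(score_pos > score_neg) + 0.5 P(tie)
auc_rank <- function(scores, y) {
  n_pos <- sum(y == 1L); n_neg <- sum(y == 0L)
  r <- rank(scores, ties.method = "average")
  (sum(r[y == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

as_binary_labels <- function(labels) {
  if (is.factor(labels)) {
    if (nlevels(droplevels(labels)) > 2L) stop("labels must have two levels")
    return(as.integer(droplevels(labels)) - 1L)
  }
  if (is.logical(labels)) return(as.integer(labels))
  u <- sort(unique(labels))
  if (!all(u %in% c(0, 1))) stop("numeric labels must be 0/1")
  as.integer(labels)
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC: AUC = %.3f (positives have %s scores; n+ = %d, n- = %d)\n",
              x$auc, x$direction, x$n_pos, x$n_neg))
  cat(sprintf("  Youden cutoff %.4g (J = %.3f): sens %.1f%%, spec %.1f%%, ppv %.1f%%, npv %.1f%%, acc %.1f%%\n",
              x$cutoff, x$youden_j, x$sensitivity, x$specificity, x$ppv,
              x$npv, x$accuracy))
  invisible(x)
}
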