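check_scores_labels <- function(scores, labels) {
  labels <- as.factor(labels)
  if (nlevels(droplevels(labels)) != 2L) {
    stop("`labels` must contain exactly two classes.", call. = FALSE)
  }
  labels <- droplevels(labels)
  if (length(scores) != length(labels)) {
    stop("`scores` and `labels` must have equal length.", call. = FALSE)
  }
  # "case" is the positive class when present; otherwise the second level
  pos_level <- if ("case" %in% levels(labels)) "case" else levels(labels)[2]
  list(scores = as.numeric(scores), positive = labels == pos_level)
}

#' Empirical ROC curve and AUC
#'
#' Sweeps all score thresholds, returning the empirical ROC as
#' `(1 - specificity, sensitivity)` points and the trapezoidal AUC, which
#' equals the Mann-Whitney concordance: the probability a random case
#' outscores a random control, ties counting one half.
#'
#' The positive class is `"case"` whenever that label is present, and the
#' second factor level otherwise.
#'
#' @param scores Numeric classifier scores (e.g. case probabilities).
#' @param labels Two-level factor (or coercible) of true classes.
#' @return List with `roc_points` (tibble `fpr`, `tpr`, both nondecreasing)
#'   and `auc`.
#' @examples
#' roc_and_auc(c(.9, .8, .2, .1), c("case", "case", "control", "control"))$auc
#' @export
roc_and_auc <- function(scores, labels) {
  cl <- check_scores_labels(scores, labels)
  pos <- cl$positive
  n_pos <- sum(pos)
  n_neg <- sum(!pos)
  ord <- order(cl$scores, decreasing = TRUE)
  s <- cl$scores[ord]
  p <- pos[ord]
  # group tied scores so the curve steps once per distinct threshold
  grp <- cumsum(c(TRUE, diff(s) != 0))
  tp <- c(0, cumsum(tapply(p, grp, sum)))
  fp <- c(0, cumsum(tapply(!p, grp, sum)))
  tpr <- tp / n_pos
  fpr <- fp / n_neg
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(
    roc_points = tibble::tibble(fpr = as.numeric(fpr), tpr = as.numeric(tpr)),
    auc = as.numeric(auc)
  )
}

#' Operating-point metrics at the Youden-optimal threshold
#'
#' Chooses the score threshold maximizing Youden's J
#' (sensitivity + specificity - 1) and reports the 2x2-table metrics there.
#' Predicted positive means `score >= threshold`. PPV or NPV with an empty
#' denominator is returned as `NA`, not zero. When all scores are tied the
#' operating point is degenerate (every subject predicted positive);
#' `degenerate = TRUE` flags it.
#'
#' @inheritParams roc_and_auc
#' @return Tibble with one row: `threshold`, `sensitivity`, `specificity`,
#'   `ppv`, `npv`, `youden_j`, `degenerate`.
#' @export
threshold_metrics <- function(scores, labels) {
  cl <- check_scores_labels(scores, labels)
  pos <- cl$positive
  thresholds <- sort(unique(cl$scores))
  best <- NULL
  for (th in thresholds) {
    pred <- cl$scores >= th
    tp <- sum(pred & pos); fn <- sum(!pred & pos)
    tn <- sum(!pred & !pos); fp <- sum(pred & !pos)
    sens <- tp / (tp + fn)
    spec <- tn / (tn + fp)
    j <- sens + spec - 1
    if (is.null(best) || j > best$j + 1e-12) {
      best <- list(th = th, tp = tp, fn = fn, tn = tn, fp = fp,
                   sens = sens, spec = spec, j = j)
    }
  }
  ppv <- if (best$tp + best$fp > 0) best$tp / (best$tp + best$fp) else NA_real_
  npv <- if (best$tn + best$fn > 0) best$tn / (best$tn + best$fn) else NA_real_
  tibble::tibble(
    threshold = best$th,
    sensitivity = best$sens,
    specificity = best$spec,
    ppv = ppv,
    npv = npv,
    youden_j = best$j,
    degenerate = length(thresholds) == 1L
  )
}
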