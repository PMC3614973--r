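#' Bootstrap-corrected internal validation of the diagnostic model
#'
#' Same-data evaluation of a flexible classifier is optimistic; internal
#' validation by bootstrapping corrects this. For each of `B` replicates,
#' subjects are resampled with replacement within each group (preserving
#' the case/control balance), the forest is refit on the resample, and only
#' the out-of-bag subjects — those not drawn — are scored. Replicate
#' ROC/AUC and Youden-threshold metrics are computed on those held-out
#' predictions; the report gives their means as the bootstrap-corrected
#' estimates, the 2.5th/97.5th percentiles as 95% confidence intervals, and
#' a vertically averaged ROC on a fixed 101-point false-positive-rate grid.
#'
#' An optimism-correction mode (`mode = "optimism"`, Harrell-style) is also
#' provided: the apparent same-data performance minus the mean over
#' replicates of (bootstrap-model performance on the resample minus on the
#' full original data).
#'
#' @param features Feature tibble (`subject_id`, `group`, 18 features), as
#'   from [cohort_features()].
#' @param B Number of bootstrap replicates (default 1000, >= 10).
#' @param mtry,n_trees Forest settings, see [fit_forest()].
#' @param seed Master seed; replicate seeds derive from it.
#' @param mode `"oob"` (default) or `"optimism"`.
#' @return Object of class `validation_report`: point estimates with CIs
#'   for AUC, sensitivity, specificity, PPV and NPV, the averaged ROC
#'   curve, and bookkeeping (`n_bootstrap`, `n_skipped`, `seed`, `mode`).
#' @export
bootstrap_validate <- function(features, B = 1000, mtry = 5, n_trees = 500,
                               seed = 1L, mode = c("oob", "optimism")) {
  mode <- match.arg(mode)
  features <- check_feature_table(features)
  if (B < 10) stop("`B` must be at least 10.", call. = FALSE)
  counts <- table(features$group)
  if (length(counts) < 2L || any(counts < 2L)) {
    stop("Both groups must be present with at least 2 subjects each.",
         call. = FALSE)
  }
  idx_by_group <- split(seq_len(nrow(features)), features$group)
  fpr_grid <- seq(0, 1, length.out = 101L)

  apparent <- NULL
  if (mode == "optimism") {
    fit0 <- fit_forest(features, mtry = mtry, n_trees = n_trees,
                       seed = seed)
    sc0 <- predict(fit0, features)
    apparent <- replicate_metrics(sc0, features$group, fpr_grid)
  }

  reps <- vector("list", B)
  n_skipped <- 0L
  for (b in seq_len(B)) {
    rep_seed <- (abs(seed) %% 19997L) * 100003L + 3000000L + b
    set.seed(rep_seed)
    boot_idx <- unlist(lapply(idx_by_group, function(ix) {
      sample(ix, length(ix), replace = TRUE)
    }), use.names = FALSE)
    oob_idx <- setdiff(seq_len(nrow(features)), boot_idx)
    oob_groups <- features$group[oob_idx]
    if (length(unique(oob_groups)) < 2L) {
      n_skipped <- n_skipped + 1L
      next
    }
    fit <- fit_forest(features[boot_idx, ], mtry = mtry, n_trees = n_trees,
                      seed = rep_seed)
    if (mode == "oob") {
      sc <- predict(fit, features[oob_idx, ])
      reps[[b]] <- replicate_metrics(sc, oob_groups, fpr_grid)
    } else {
      sc_boot <- predict(fit, features[boot_idx, ])
      sc_orig <- predict(fit, features)
      m_boot <- replicate_metrics(sc_boot, features$group[boot_idx], fpr_grid)
      m_orig <- replicate_metrics(sc_orig, features$group, fpr_grid)
      reps[[b]] <- purrr::map2(m_boot, m_orig, `-`)  # optimism per metric
    }
  }
  if (n_skipped > 0.2 * B) {
    stop(sprintf(
      "%d of %d bootstrap replicates had an out-of-bag set missing a group.",
      n_skipped, B
    ), call. = FALSE)
  }
  reps <- reps[!vapply(reps, is.null, logical(1))]

  metric_names <- c("auc", "sensitivity", "specificity", "ppv", "npv")
  draw_mat <- vapply(reps, function(r) unlist(r[metric_names]),
                     numeric(length(metric_names)))
  draw_mat <- matrix(draw_mat, nrow = length(metric_names),
                     dimnames = list(metric_names, NULL))

  if (mode == "oob") {
    est <- apply(draw_mat, 1L, mean, na.rm = TRUE)
    ci <- apply(draw_mat, 1L, stats::quantile, probs = c(0.025, 0.975),
                na.rm = TRUE)
    tpr_mat <- vapply(reps, `[[`, numeric(length(fpr_grid)), "tpr_grid")
    roc_curve <- tibble::tibble(fpr = fpr_grid, tpr = rowMeans(tpr_mat))
  } else {
    optimism <- apply(draw_mat, 1L, mean, na.rm = TRUE)
    est <- pmin(1, pmax(0, unlist(apparent[metric_names]) - optimism))
    names(est) <- metric_names
    ci_width <- apply(draw_mat, 1L, stats::quantile, probs = c(0.025, 0.975),
                      na.rm = TRUE)
    half <- (ci_width[2, ] - ci_width[1, ]) / 2
    ci <- rbind(pmax(0, est - half), pmin(1, est + half))
    dimnames(ci) <- list(c("lo", "hi"), metric_names)
    tpr_mat <- vapply(reps, `[[`, numeric(length(fpr_grid)), "tpr_grid")
    roc_curve <- tibble::tibble(
      fpr = fpr_grid,
      tpr = pmin(1, pmax(0, apparent$tpr_grid - rowMeans(tpr_mat)))
    )
  }
  metrics <- tibble::tibble(
    metric = metric_names,
    estimate = as.numeric(est[metric_names]),
    ci_lo = as.numeric(ci[1, metric_names]),
    ci_hi = as.numeric(ci[2, metric_names])
  )
  structure(
    list(
      metrics = metrics,
      roc_curve = roc_curve,
      n_bootstrap = B,
      n_used = length(reps),
      n_skipped = n_skipped,
      mtry = mtry,
      n_trees = n_trees,
      seed = seed,
      mode = mode
    ),
    class = "validation_report"
  )
}

# AUC, Youden metrics and the ROC interpolated on the fpr grid, for one
# replicate's held-out scores.
replicate_metrics <- function(scores, labels, fpr_grid) {
  roc <- roc_and_auc(scores, labels)
  tm <- threshold_metrics(scores, labels)
  # step-function (staircase) interpolation of tpr at each grid fpr
  tpr_grid <- vapply(fpr_grid, function(f) {
    max(roc$roc_points$tpr[roc$roc_points$fpr <= f + 1e-12])
  }, numeric(1))
  list(
    auc = roc$auc,
    sensitivity = tm$sensitivity,
    specificity = tm$specificity,
    ppv = tm$ppv,
    npv = tm$npv,
    tpr_grid = tpr_grid
  )
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf(
    "<validation_report> %s bootstrap, B = %d (%d used, %d skipped), seed %d\n",
    x$mode, x$n_bootstrap, x$n_used, x$n_skipped, x$seed
  ))
  m <- x$metrics
  for (i in seq_len(nrow(m))) {
    cat(sprintf("  %-12s %.3f [95%% CI %.3f-%.3f]\n",
                m$metric[i], m$estimate[i], m$ci_lo[i], m$ci_hi[i]))
  }
  invisible(x)
}

#' Tidy a validation report
#'
#' @param x A `validation_report`.
#' @param ... Unused.
#' @return Tibble with columns `metric`, `estimate`, `ci_lo`, `ci_hi`.
#' @export
tidy.validation_report <- function(x, ...) x$metrics

#' One-row summary of a validation report
#'
#' @param x A `validation_report`.
#' @param ... Unused.
#' @return One-row tibble: point estimates plus replicate bookkeeping.
#' @export
glance.validation_report <- function(x, ...) {
  est <- stats::setNames(x$metrics$estimate, x$metrics$metric)
  tibble::tibble(
    auc = est[["auc"]],
    sensitivity = est[["sensitivity"]],
    specificity = est[["specificity"]],
    ppv = est[["ppv"]],
    npv = est[["npv"]],
    n_bootstrap = x$n_bootstrap,
    n_used = x$n_used,
    n_skipped = x$n_skipped,
    mode = x$mode
  )
}

#' Serialize a validation report to JSON
#'
#' Point estimates with CIs, the averaged ROC grid, and the settings.
#'
#' @param report A `validation_report`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_validation_json <- function(report, path) {
  payload <- list(
    metrics = report$metrics,
    roc_curve = report$roc_curve,
    settings = list(
      n_bootstrap = report$n_bootstrap,
      n_used = report$n_used,
      n_skipped = report$n_skipped,
      mtry = report$mtry,
      n_trees = report$n_trees,
      seed = report$seed,
      mode = report$mode
    )
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
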