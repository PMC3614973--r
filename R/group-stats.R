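#' Per-feature two-sample Student t-tests
#'
#' Compares cases and controls on each of the 18 network features with the
#' pooled-variance (Student) independent t-test, two-sided, with no
#' multiplicity adjustment by default — single network characteristics are
#' expected to show little univariate separation even when the multivariable
#' model discriminates well. An optional Holm adjustment is available.
#'
#' Features with zero pooled variance are flagged and their p-value
#' omitted.
#'
#' @param features Feature tibble (`group` plus the 18 feature columns).
#' @param adjust `"none"` (default) or `"holm"`.
#' @return Tibble with one row per feature: group means and SDs, `t`,
#'   `df`, `p_value`, `degenerate`.
#' @export
per_feature_ttest <- function(features, adjust = c("none", "holm")) {
  adjust <- match.arg(adjust)
  features <- check_feature_table(features)
  counts <- table(features$group)
  if (any(counts < 2L)) {
    stop("Need at least 2 subjects per group.", call. = FALSE)
  }
  g1 <- levels(features$group)[1]
  g2 <- levels(features$group)[2]
  rows <- purrr::map(feature_names(), function(f) {
    x1 <- features[[f]][features$group == g1]
    x2 <- features[[f]][features$group == g2]
    pooled_var <- ((length(x1) - 1) * stats::var(x1) +
                     (length(x2) - 1) * stats::var(x2)) /
      (length(x1) + length(x2) - 2)
    if (pooled_var == 0) {
      return(tibble::tibble(
        feature = f,
        mean_1 = mean(x1), sd_1 = stats::sd(x1),
        mean_2 = mean(x2), sd_2 = stats::sd(x2),
        t = NA_real_, df = length(x1) + length(x2) - 2,
        p_value = NA_real_, degenerate = TRUE
      ))
    }
    tt <- stats::t.test(x1, x2, var.equal = TRUE)
    tibble::tibble(
      feature = f,
      mean_1 = mean(x1), sd_1 = stats::sd(x1),
      mean_2 = mean(x2), sd_2 = stats::sd(x2),
      t = unname(tt$statistic), df = unname(tt$parameter),
      p_value = tt$p.value, degenerate = FALSE
    )
  })
  out <- dplyr::bind_rows(rows)
  names(out)[names(out) == "mean_1"] <- paste0("mean_", g1)
  names(out)[names(out) == "sd_1"] <- paste0("sd_", g1)
  names(out)[names(out) == "mean_2"] <- paste0("mean_", g2)
  names(out)[names(out) == "sd_2"] <- paste0("sd_", g2)
  if (adjust == "holm") {
    out$p_adjusted <- stats::p.adjust(out$p_value, method = "holm")
  }
  out
}

#' Pearson correlation matrix of the 18 features
#'
#' Quantifies redundancy among the network characteristics across subjects.
#' Constant features produce `NA` rows/columns with a warning rather than
#' an error.
#'
#' @param features Feature tibble.
#' @return 18x18 symmetric correlation matrix with unit diagonal, feature
#'   names as dimnames.
#' @export
feature_correlation <- function(features) {
  features <- check_feature_table(features)
  if (nrow(features) < 3L) {
    stop("Need at least 3 subjects for a correlation matrix.", call. = FALSE)
  }
  x <- as.matrix(features[feature_names()])
  sds <- apply(x, 2L, stats::sd)
  if (any(sds == 0)) {
    warning("Constant feature(s) have undefined correlations: ",
            paste(feature_names()[sds == 0], collapse = ", "))
  }
  r <- suppressWarnings(stats::cor(x))
  diag(r) <- 1
  r
}

#' Export comparisons / correlations to CSV
#'
#' @param x Tibble from [per_feature_ttest()] or matrix from
#'   [feature_correlation()].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_stats_csv <- function(x, path) {
  if (is.matrix(x)) {
    utils::write.csv(cbind(feature = rownames(x), as.data.frame(x)), path,
                     row.names = FALSE, quote = FALSE)
  } else {
    utils::write.csv(x, path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
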