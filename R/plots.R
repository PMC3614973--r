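#' Plot a bootstrap-averaged ROC curve
#'
#' @param object A `validation_report`.
#' @param ... Unused.
#' @return A ggplot: averaged ROC with the chance diagonal and the
#'   corrected AUC in the subtitle.
#' @export
autoplot.validation_report <- function(object, ...) {
  auc <- object$metrics$estimate[object$metrics$metric == "auc"]
  ggplot2::ggplot(object$roc_curve, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(intercept = 0, slope = 1, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step(linewidth = 0.8) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "1 - specificity", y = "Sensitivity",
      title = "Bootstrap-corrected ROC",
      subtitle = sprintf("corrected AUC = %.3f (%s, B = %d)",
                         auc, object$mode, object$n_bootstrap)
    ) +
    ggplot2::theme_minimal()
}

#' Plot group power spectral densities
#'
#' @param psd_by_group Named list of tibbles from [compute_psd()], one per
#'   group.
#' @param relative Plot relative (default) or absolute power.
#' @return A ggplot of channel-averaged spectra per group.
#' @export
plot_psd <- function(psd_by_group, relative = TRUE) {
  df <- dplyr::bind_rows(psd_by_group, .id = "group")
  value <- if (relative) "relative_power" else "absolute_power"
  df <- dplyr::summarise(
    dplyr::group_by(df, .data$group, .data$frequency),
    power = mean(.data[[value]]),
    .groups = "drop"
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$frequency, y = .data$power,
                                   colour = .data$group)) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "Frequency (Hz)",
      y = if (relative) "Relative power" else
        expression("Power (" * units^2 / Hz * ")"),
      title = "Channel-averaged power spectral density"
    ) +
    ggplot2::theme_minimal()
}

#' Heatmap of the feature correlation matrix
#'
#' @param r Matrix from [feature_correlation()].
#' @return A ggplot heatmap of Pearson correlations.
#' @export
plot_feature_correlation <- function(r) {
  df <- tidyr::pivot_longer(
    dplyr::mutate(tibble::as_tibble(r), row = factor(rownames(r),
                                                     levels = rownames(r))),
    -dplyr::all_of("row"), names_to = "col", values_to = "r"
  )
  df$col <- factor(df$col, levels = rownames(r))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "Pearson r",
                  title = "Feature correlation matrix") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       hjust = 1, vjust = 0.5))
}
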