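# ggplot2 displays for the result objects.

#' Plot precision-recall and ROC curves for an evaluation
#'
#' @param object A `network_evaluation`.
#' @param curve `"pr"` (default) or `"roc"`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot network_evaluation
#' @export
autoplot.network_evaluation <- function(object, curve = c("pr", "roc"), ...) {
  curve <- match.arg(curve)
  df <- tidy(object)
  if (curve == "pr") {
    ggplot2::ggplot(df, ggplot2::aes(x = .data$recall, y = .data$precision)) +
      ggplot2::geom_step(direction = "hv") +
      ggplot2::geom_hline(yintercept = object$prior, linetype = "dashed") +
      ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
      ggplot2::labs(
        x = "Recall", y = "Precision",
        title = sprintf("auPRC = %.3g, log2(auPRC/prior) = %.2f",
                        object$auprc, object$log2_auprc_over_prior)
      ) +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(df, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
      ggplot2::geom_line() +
      ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
      ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
      ggplot2::labs(x = "False positive rate", y = "True positive rate",
                    title = sprintf("auROC = %.3g", object$auroc)) +
      ggplot2::theme_minimal()
  }
}

#' Heatmap of pairwise workflow win proportions
#'
#' Rows and columns are workflows; cell color is the proportion of shared
#' datasets on which the row workflow scores higher, with significant
#' comparisons (BH-adjusted p at or below the comparison's FDR threshold)
#' marked by an asterisk.
#'
#' @param object A `workflow_comparison`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot workflow_comparison
#' @export
autoplot.workflow_comparison <- function(object, ...) {
  df <- object$pairs
  ord <- object$wins$workflow
  df$workflow_a <- factor(df$workflow_a, levels = rev(ord))
  df$workflow_b <- factor(df$workflow_b, levels = ord)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$workflow_b, y = .data$workflow_a,
                                   fill = .data$win_prop)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(
      data = df[df$significant, , drop = FALSE],
      ggplot2::aes(label = "*"), size = 3
    ) +
    ggplot2::scale_fill_gradient2(midpoint = 0.5, limits = c(0, 1),
                                  name = "Win prop.") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5, hjust = 1))
}

#' Boxplots of workflow scores across datasets
#'
#' Workflows ordered by median score, the display used to compare overall
#' workflow performance.
#'
#' @param scores Score tibble from [benchmark_corpus()].
#' @param score_col Score column, default `log2_auprc_over_prior`.
#' @return A ggplot.
#' @export
plot_score_distribution <- function(scores,
                                    score_col = "log2_auprc_over_prior") {
  stopifnot(all(c("workflow", score_col) %in% names(scores)))
  med <- scores |>
    group_by(.data$workflow) |>
    summarise(m = median(.data[[score_col]]), .groups = "drop") |>
    arrange(.data$m)
  scores$workflow <- factor(scores$workflow, levels = med$workflow)
  ggplot2::ggplot(scores, ggplot2::aes(x = .data[[score_col]],
                                       y = .data$workflow)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "log2(auPRC / prior)", y = NULL) +
    ggplot2::theme_minimal()
}
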