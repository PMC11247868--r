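#' Plot helpers
#'
#' ggplot2 views of the main result objects: ROC curve of the diagnostic
#' score, score-by-stage distributions, and the marker-count sweep curves.
#'
#' @name plots
NULL

#' ROC curve of methylation scores
#'
#' @param scores tibble `sample_id, methylation_score`.
#' @param samples sample sheet with `label`.
#' @return A ggplot object.
#' @export
plot_roc <- function(scores, samples) {
  df <- inner_join(scores, samples, by = "sample_id") |>
    mutate(case = .data$label != "healthy") |>
    arrange(desc(.data$methylation_score)) |>
    mutate(tpr = cumsum(.data$case) / sum(.data$case),
           fpr = cumsum(!.data$case) / sum(!.data$case))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(linetype = "dashed", colour = "grey60") +
    ggplot2::labs(x = "1 - specificity", y = "sensitivity",
                  title = sprintf("AUC = %.3f",
                                  roc_auc(df$methylation_score, df$case))) +
    ggplot2::theme_minimal()
}

#' Methylation score by disease stage
#'
#' @param scores tibble `sample_id, methylation_score`.
#' @param samples sample sheet with `label`, `stage`.
#' @param threshold optional `mt_threshold`; drawn as a horizontal line.
#' @return A ggplot object.
#' @export
plot_score_by_stage <- function(scores, samples, threshold = NULL) {
  df <- inner_join(scores, samples, by = "sample_id") |>
    mutate(stratum = if_else(.data$label == "healthy", "healthy",
                             paste("stage", .data$stage)))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$stratum,
                                        y = .data$methylation_score)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.3, size = 0.6) +
    ggplot2::labs(x = NULL, y = "methylation score") +
    ggplot2::theme_minimal()
  if (!is.null(threshold)) {
    p <- p + ggplot2::geom_hline(yintercept = threshold$cutoff,
                                 linetype = "dashed", colour = "red")
  }
  p
}

#' Marker-count sweep curves
#'
#' @param sweep result of [marker_count_sweep()].
#' @return A ggplot object (diagnostic AUC vs X).
#' @export
plot_sweep <- function(sweep) {
  df <- tidyr::pivot_longer(sweep$diagnostic, c("auc_train", "auc_test"),
                            names_to = "cohort", values_to = "auc",
                            names_prefix = "auc_")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$top_x, y = .data$auc,
                                   colour = .data$cohort)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "top X markers per class", y = "AUC") +
    ggplot2::theme_minimal()
}

#' @rdname plots
#' @param object an `mt_eval` object.
#' @param ... unused.
#' @method autoplot mt_eval
#' @export
autoplot.mt_eval <- function(object, ...) {
  df <- object$by_class_stage
  ggplot2::ggplot(df, ggplot2::aes(x = .data$stage, y = .data$estimate)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$conf_low,
                                        ymax = .data$conf_high), width = 0.3) +
    ggplot2::facet_wrap(~class) +
    ggplot2::labs(x = "stage", y = "sensitivity (Wilson 95% CI)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
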