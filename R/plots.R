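#' Plot metric curves along the decision-threshold grid
#'
#' Accuracy, precision, recall and F1 as the classification threshold is
#' raised from 0.5 towards 1; the chosen threshold is marked.
#'
#' @param sweep a `threshold_sweep` from [threshold_postprocess()].
#' @return A ggplot object.
#' @export
plot_threshold_curves <- function(sweep) {
  df <- sweep$curves |>
    tidyr::pivot_longer(c("accuracy", "precision", "recall", "f1"),
                        names_to = "metric", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$threshold, y = .data$value,
                                   colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = sweep$threshold, linetype = "dashed") +
    ggplot2::labs(x = "classification threshold", y = NULL,
                  title = sprintf("threshold sweep (chosen %.2f)", sweep$threshold)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.threshold_sweep <- function(object, ...) plot_threshold_curves(object)

#' Plot a gold-standard retrieval curve with its R50 mark
#'
#' @param r50 result of [r50_curve()].
#' @param gold_size size of the gold set (for the half-way line); optional.
#' @return A ggplot object.
#' @export
plot_r50_curve <- function(r50, gold_size = NULL) {
  p <- ggplot2::ggplot(r50$curve, ggplot2::aes(x = .data$k, y = .data$hits)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "top-ranked regulons", y = "gold-standard TFs retrieved") +
    ggplot2::theme_minimal()
  if (!is.na(r50$r50)) {
    p <- p + ggplot2::geom_vline(xintercept = r50$r50, linetype = "dashed")
  }
  if (!is.null(gold_size)) {
    p <- p + ggplot2::geom_hline(yintercept = gold_size / 2, linetype = "dotted")
  }
  p
}

#' Plot candidate-edge counts across pipeline stages
#'
#' The stage-wise shrinkage of the candidate set through the importance,
#' correlation, motif and ChIP stages.
#'
#' @param report the `report` tibble of [run_pipeline_objects()].
#' @return A ggplot object.
#' @export
plot_stage_counts <- function(report) {
  df <- report |> mutate(stage = factor(.data$stage, levels = .data$stage))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$stage, y = .data$edges)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "candidate edges") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
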