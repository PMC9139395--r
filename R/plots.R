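# ggplot2 views of the standard result shapes.

#' Variance vs mean density, with selected ROIs highlighted
#'
#' The classic reader-study triage view: each point is one ROI at its
#' pooled mean sTILs density and density sample variance; ROIs picked by
#' [stratified_select()] are overplotted as solid triangles. Dashed
#' vertical lines mark the 10% and 40% infiltration-bin thresholds.
#'
#' @param aggregates Tibble from [aggregate_rois()].
#' @param selection Optional `"stils_selection"` to highlight.
#' @param log_variance Plot variance on a log10 axis (zero variances are
#'   shown at the axis floor). Default `TRUE`.
#' @return A ggplot object.
#' @export
plot_variance_vs_mean <- function(aggregates, selection = NULL, log_variance = TRUE) {
  df <- dplyr::filter(aggregates, !is.na(.data$mean_density), !is.na(.data$sample_variance))
  if (log_variance) {
    floor_v <- max(1e-2, min(df$sample_variance[df$sample_variance > 0], na.rm = TRUE) / 2)
    df$sample_variance <- pmax(df$sample_variance, floor_v)
  }
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$mean_density, y = .data$sample_variance)) +
    ggplot2::geom_point(shape = 1, alpha = 0.6) +
    ggplot2::geom_vline(xintercept = c(10, 40), linetype = "dashed") +
    ggplot2::labs(
      x = "Mean sTILs density (%)",
      y = "sTILs density sample variance",
      title = "Per-ROI variance vs mean density"
    )
  if (!is.null(selection)) {
    sel_df <- dplyr::semi_join(df, tidy(selection), by = "roi_id")
    p <- p + ggplot2::geom_point(data = sel_df, shape = 17, size = 2)
  }
  if (log_variance) p <- p + ggplot2::scale_y_log10()
  p
}

#' Paired crowd-vs-expert statistic plot
#'
#' Each selected ROI contributes a vertical segment from its crowd value
#' to its expert value, positioned at the crowd mean density; ROIs with
#' no calculable expert value are open circles with no segment.
#'
#' @param deltas Tibble from [paired_deltas()].
#' @param statistic_name Axis label for the statistic.
#' @return A ggplot object.
#' @export
plot_paired_deltas <- function(deltas, statistic_name = "statistic") {
  paired <- dplyr::filter(deltas, !is.na(.data$expert_value))
  unpaired <- dplyr::filter(deltas, is.na(.data$expert_value))
  ggplot2::ggplot(paired, ggplot2::aes(x = .data$crowd_mean_density)) +
    ggplot2::geom_segment(ggplot2::aes(
      xend = .data$crowd_mean_density,
      y = .data$crowd_value, yend = .data$expert_value
    ), alpha = 0.5) +
    ggplot2::geom_point(ggplot2::aes(y = .data$crowd_value, colour = "Crowd")) +
    ggplot2::geom_point(ggplot2::aes(y = .data$expert_value, colour = "Experts"), shape = 17) +
    ggplot2::geom_point(
      data = unpaired,
      ggplot2::aes(y = .data$crowd_value, colour = "Crowd"),
      shape = 1
    ) +
    ggplot2::geom_vline(xintercept = c(10, 40), linetype = "dashed") +
    ggplot2::labs(
      x = "Crowd mean sTILs density (%)",
      y = statistic_name,
      colour = NULL,
      title = paste("Crowd vs experts:", statistic_name)
    )
}

#' Bar chart of a stratified selection
#'
#' @param object A `"stils_selection"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @importFrom ggplot2 autoplot
#' @method autoplot stils_selection
#' @export
autoplot.stils_selection <- function(object, ...) {
  e <- object$entries
  ggplot2::ggplot(e, ggplot2::aes(x = .data$density_bin, fill = .data$stratum)) +
    ggplot2::geom_bar(position = "dodge") +
    ggplot2::labs(
      x = "sTILs density bin", y = "selected ROIs", fill = "stratum",
      title = "Stratified selection by bin and stratum"
    )
}
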