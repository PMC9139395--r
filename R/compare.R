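# Cohort comparison artifacts: median (IQR) summary tables by cohort view
# and infiltration bin, majority-label frequency tables, and paired
# per-ROI crowd-vs-expert deltas.

#' Median (IQR) of a per-ROI statistic by infiltration bin
#'
#' Summarizes one per-ROI statistic (density sample variance or label
#' entropy) for one cohort view as median and quartiles, in an
#' all-densities cell plus one cell per infiltration bin. For
#' `sample_variance`, ROIs with an absent variance are excluded from every
#' cell. ROIs lacking a mean density (hence a bin) contribute only to the
#' all-densities cell.
#'
#' When comparing cohorts on the same ROIs (expert panel vs crowd), pass
#' `bins`: a `roi_id` to `density_bin` map — typically the crowd's bins —
#' so that both views are stratified identically, matched on the crowd
#' pathologists' mean density.
#'
#' @param aggregates Tibble from [aggregate_rois()] for one cohort.
#' @param statistic `"sample_variance"` or `"entropy"`.
#' @param view Label for this cohort view (e.g. `"Crowd-All"`,
#'   `"Crowd-Select"`, `"Experts"`), carried into the output.
#' @param bins Optional tibble (`roi_id`, `density_bin`) overriding the
#'   aggregates' own bins for stratification.
#' @param quantile_type Quantile convention passed to [stats::quantile()];
#'   default 7 (linear interpolation between order statistics).
#' @return Tibble of cells: `view`, `bin` (`"all"` plus [density_bins()]),
#'   `n`, `median`, `q1`, `q3`. Empty cells are omitted.
#' @export
summarize_statistic <- function(aggregates,
                                statistic = c("sample_variance", "entropy"),
                                view = "cohort",
                                bins = NULL,
                                quantile_type = 7) {
  statistic <- match.arg(statistic)
  df <- tibble::as_tibble(aggregates)
  if (!is.null(bins)) {
    df$density_bin <- NULL
    df <- dplyr::left_join(df, bins[c("roi_id", "density_bin")], by = "roi_id")
  }
  values <- df[[statistic]]
  keep <- !is.na(values)
  df <- df[keep, ]
  values <- values[keep]

  cell <- function(v, bin_name) {
    if (length(v) == 0) return(NULL)
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), type = quantile_type, names = FALSE)
    tibble::tibble(
      view = view, bin = bin_name, n = length(v),
      median = q[2], q1 = q[1], q3 = q[3]
    )
  }
  cells <- c(
    list(cell(values, "all")),
    purrr::map(density_bins(), function(b) {
      cell(values[!is.na(df$density_bin) & df$density_bin == b], b)
    })
  )
  dplyr::bind_rows(cells)
}

#' Render summary cells as "median (q1–q3)" text
#'
#' Pivots cells from [summarize_statistic()] into one row per view with
#' one column per bin, each formatted `median (q1–q3)` at the requested
#' precision — the familiar reporting layout of reader-study summary
#' tables.
#'
#' @param cells Tibble of cells, possibly several views bound together.
#' @param digits Decimal places; default 2.
#' @return Tibble, one row per view.
#' @export
format_summary <- function(cells, digits = 2) {
  fmt <- function(x) formatC(x, format = "f", digits = digits)
  cells |>
    dplyr::mutate(
      text = paste0(fmt(.data$median), " (", fmt(.data$q1), "–", fmt(.data$q3), ")"),
      bin = factor(.data$bin, levels = c("all", density_bins()))
    ) |>
    dplyr::select("view", "bin", "text") |>
    tidyr::pivot_wider(names_from = "bin", values_from = "text")
}

#' Frequency of majority ROI labels
#'
#' Counts the rendered majority label (ties joined by `" *AND* "`) across
#' ROIs, with percentages of the total.
#'
#' @param aggregates Tibble from [aggregate_rois()].
#' @return Tibble: `majority_label`, `n`, `percent`, ordered by the
#'   canonical rendering.
#' @export
majority_label_frequencies <- function(aggregates) {
  if (nrow(aggregates) == 0) stop("no aggregates to tabulate", call. = FALSE)
  aggregates |>
    dplyr::count(.data$majority_label, name = "n") |>
    dplyr::mutate(percent = .data$n / sum(.data$n) * 100) |>
    dplyr::arrange(.data$majority_label)
}

#' Paired per-ROI crowd-vs-expert deltas
#'
#' Matches the two cohorts' aggregates on `roi_id` over the crowd side
#' (typically the selected ROIs) and reports, per ROI, the crowd value,
#' the expert value, and their difference (expert minus crowd) for the
#' chosen statistic. The expert value is absent where the statistic is
#' not calculable on the expert side (e.g. fewer than two expert density
#' scores), and then the delta is absent too. The crowd mean density is
#' carried along as the natural plotting position.
#'
#' @param crowd_aggregates,expert_aggregates Tibbles from
#'   [aggregate_rois()]; every expert `roi_id` must appear on the crowd
#'   side.
#' @param statistic `"sample_variance"` or `"entropy"`.
#' @return Tibble: `roi_id`, `crowd_mean_density`, `crowd_value`,
#'   `expert_value`, `delta`.
#' @export
paired_deltas <- function(crowd_aggregates, expert_aggregates,
                          statistic = c("sample_variance", "entropy")) {
  statistic <- match.arg(statistic)
  orphans <- setdiff(expert_aggregates$roi_id, crowd_aggregates$roi_id)
  if (length(orphans) > 0) {
    stop(
      "expert ROIs missing from the crowd side: ",
      paste(utils::head(orphans, 5), collapse = ", "),
      call. = FALSE
    )
  }
  crowd <- tibble::tibble(
    roi_id = crowd_aggregates$roi_id,
    crowd_mean_density = crowd_aggregates$mean_density,
    crowd_value = crowd_aggregates[[statistic]]
  )
  expert <- tibble::tibble(
    roi_id = expert_aggregates$roi_id,
    expert_value = expert_aggregates[[statistic]]
  )
  crowd |>
    dplyr::left_join(expert, by = "roi_id") |>
    dplyr::mutate(delta = .data$expert_value - .data$crowd_value)
}
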