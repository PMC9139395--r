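# Per-ROI pooling of reader annotations: label counts, Shannon entropy,
# tie-aware majority labels, density mean/variance, and density binning.

#' Shannon entropy of reader label counts
#'
#' For an ROI labelled by several readers, entropy measures the spread of
#' the four-category label distribution:
#' \deqn{H = -\sum_i p_i \log p_i,}
#' where \eqn{p_i} is the fraction of readers choosing label \eqn{i} and
#' zero-count labels contribute nothing. It is zero exactly when all
#' readers agree and maximal (\eqn{\log 4} in natural units) when the four
#' labels are equally frequent — a variance analogue for categorical data.
#'
#' @param counts Non-negative numeric vector of per-label reader counts
#'   (any length; for ROI labels, length 4 in the [roi_labels()] order).
#'   At least one count must be positive.
#' @param base Logarithm base; defaults to `exp(1)` (nats), the convention
#'   used throughout the package.
#' @return Entropy as a single non-negative number.
#' @examples
#' label_entropy(c(1, 3, 2, 0)) # prints as 1.01
#' label_entropy(c(8, 0, 0, 0)) # perfect agreement
#' @export
label_entropy <- function(counts, base = exp(1)) {
  if (length(counts) == 0 || any(is.na(counts)) || any(counts < 0)) {
    stop("counts must be non-negative and free of NA", call. = FALSE)
  }
  total <- sum(counts)
  if (total == 0) stop("all label counts are zero: no annotations for this ROI", call. = FALSE)
  p <- counts[counts > 0] / total
  -sum(p * log(p, base = base)) + 0 # + 0 normalizes IEEE -0 at perfect agreement
}

#' Sample variance of reader density scores
#'
#' The unbiased sample variance (denominator \eqn{n - 1}) of the density
#' scores contributed for one ROI. At least two scores are required: with
#' fewer, the variance is reported absent (`NA`), never zero — an ROI
#' scored once carries no dispersion information.
#'
#' @param scores Numeric vector of density percentages; `NA`s are dropped.
#' @return Sample variance, or `NA_real_` when fewer than two scores are
#'   present.
#' @examples
#' sample_variance(c(0, 90, 90)) # 2700
#' @export
sample_variance <- function(scores) {
  scores <- scores[!is.na(scores)]
  if (length(scores) < 2) return(NA_real_)
  stats::var(scores)
}

#' Majority label(s) of an ROI
#'
#' All labels attaining the maximal reader count, in canonical
#' [roi_labels()] order. Ties are real in reader data and are kept: a
#' three-way tie returns three labels.
#'
#' @param counts Numeric vector of length 4, reader counts per label in
#'   [roi_labels()] order; at least one positive.
#' @return Character vector of the modal label(s).
#' @examples
#' majority_labels(c(3, 1, 2, 0))
#' majority_labels(c(2, 2, 2, 0)) # three-way tie
#' @export
majority_labels <- function(counts) {
  if (length(counts) != 4 || any(is.na(counts)) || any(counts < 0)) {
    stop("counts must be 4 non-negative values in roi_labels() order", call. = FALSE)
  }
  if (sum(counts) == 0) stop("all label counts are zero: no annotations for this ROI", call. = FALSE)
  roi_labels()[counts == max(counts)]
}

#' Render majority labels as a single string
#'
#' Tied majority labels are joined with `" *AND* "`, the rendering used in
#' frequency tables.
#'
#' @param labels Character vector of majority labels in canonical order.
#' @return Single string.
#' @examples
#' render_majority(majority_labels(c(2, 2, 0, 0)))
#' @export
render_majority <- function(labels) {
  paste(labels, collapse = " *AND* ")
}

#' Density bin levels
#'
#' The three clinically motivated sTILs infiltration strata:
#' low (`LE10`, 10% or less), moderate (`GT10_LE40`, more than 10% up to
#' 40%), and high (`GT40`, more than 40%).
#'
#' @return Character vector of bin level names.
#' @export
density_bins <- function() c("LE10", "GT10_LE40", "GT40")

#' Assign mean densities to infiltration bins
#'
#' Boundaries are closed on the right: a mean of exactly 10 is low
#' infiltration ("10% or less"), exactly 40 is moderate. A mean of 0 falls
#' in the low bin.
#'
#' @param mean_density Numeric vector of mean densities in \[0, 100\];
#'   `NA` passes through as `NA`.
#' @return Factor with levels [density_bins()].
#' @examples
#' assign_density_bin(c(0, 10, 10.5, 40, 64.2))
#' @export
assign_density_bin <- function(mean_density) {
  if (any(mean_density < 0 | mean_density > 100, na.rm = TRUE)) {
    stop("mean_density must lie in [0, 100]", call. = FALSE)
  }
  cut(
    mean_density,
    breaks = c(-Inf, 10, 40, Inf),
    labels = density_bins(),
    right = TRUE
  )
}

#' Pool reader annotations per ROI
#'
#' Collapses a table of per-(ROI, reader) records into one row per ROI:
#' label counts and fractions, Shannon label entropy, tie-aware majority
#' label, the number of density scores present, their mean and unbiased
#' sample variance, and the infiltration bin of the mean. The mean is
#' absent when no density was scored; the variance additionally requires
#' at least two scores; the bin follows the mean.
#'
#' By default density scores recorded under non-evaluable labels (present
#' in lenient pilot data) contribute to the mean and variance; set
#' `evaluable_densities_only = TRUE` to restrict pooling to scores under
#' evaluable labels.
#'
#' @param records Data frame of annotation records (as returned by
#'   [read_annotations()] or [simulate_cohort()]); may cover many ROIs.
#' @param evaluable_densities_only Drop density scores recorded under
#'   non-evaluable labels before pooling. Default `FALSE`.
#' @return Tibble with one row per `roi_id`: `n_labels`, `n_<label>`
#'   counts (4 columns), `entropy`, `majority_label` (rendered, ties
#'   joined by `" *AND* "`), `n_majority` (number of tied modal labels),
#'   `n_density`, `mean_density`, `sample_variance`, `density_bin`.
#' @examples
#' recs <- tibble::tibble(
#'   roi_id = "r1", reader_id = as.character(1:4), cohort = "crowd",
#'   roi_label = "Intra-Tumoral Stroma", percent_stroma = 50,
#'   stils_density = c(0, 0, 0, 40)
#' )
#' aggregate_rois(recs)
#' @export
aggregate_rois <- function(records, evaluable_densities_only = FALSE) {
  if (nrow(records) == 0) stop("no annotation records to aggregate", call. = FALSE)
  records <- tibble::as_tibble(records)
  records$roi_label <- as_roi_label(records$roi_label)

  density <- records$stils_density
  if (evaluable_densities_only) {
    density[!(records$roi_label %in% roi_labels()[1:2])] <- NA_real_
  }
  records$.density <- density

  count_cols <- paste0("n_", c("its", "im", "twnis", "or"))

  out <- records |>
    dplyr::group_by(.data$roi_id) |>
    dplyr::summarise(
      n_labels = dplyr::n(),
      counts = list(as.integer(table(.data$roi_label))),
      entropy = label_entropy(table(.data$roi_label)),
      majority_label = render_majority(majority_labels(as.integer(table(.data$roi_label)))),
      n_majority = length(majority_labels(as.integer(table(.data$roi_label)))),
      n_density = sum(!is.na(.data$.density)),
      mean_density = ifelse(.data$n_density > 0, mean(.data$.density, na.rm = TRUE), NA_real_),
      sample_variance = sample_variance(.data$.density),
      .groups = "drop"
    )
  counts <- do.call(rbind, out$counts)
  colnames(counts) <- count_cols
  out$counts <- NULL
  out <- dplyr::bind_cols(out, tibble::as_tibble(counts))
  out$density_bin <- assign_density_bin(out$mean_density)
  dplyr::relocate(
    out,
    dplyr::all_of(count_cols),
    .after = "n_labels"
  )
}

#' Pool one ROI's annotations
#'
#' Single-ROI convenience wrapper around [aggregate_rois()]; errors if the
#' records span more than one `roi_id`.
#'
#' @inheritParams aggregate_rois
#' @return One-row tibble (see [aggregate_rois()] for columns).
#' @export
aggregate_roi <- function(records, evaluable_densities_only = FALSE) {
  if (nrow(records) == 0) stop("no annotation records to aggregate", call. = FALSE)
  if (dplyr::n_distinct(records$roi_id) != 1) {
    stop("records span multiple roi_id values; use aggregate_rois()", call. = FALSE)
  }
  aggregate_rois(records, evaluable_densities_only = evaluable_densities_only)
}
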