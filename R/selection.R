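# Stratified selection of high- and low-variability ROIs for expert review.
#
# ROIs without a calculable variance are filtered out first; the survivors
# are stratified by infiltration bin, ranked jointly on density variance
# and label entropy, and the extremes of each bin are drawn at a high:low
# ratio, then split evenly into two training batches.

#' Selection configuration
#'
#' @param per_bin_quota Named integer vector, ROIs to select per
#'   infiltration bin, names [density_bins()]. The defaults (27, 25, 20)
#'   total 72 ROIs.
#' @param high_low_ratio Length-2 positive numeric, the high:low selection
#'   ratio within each bin. Default `c(2, 1)`: two high-variability ROIs
#'   for each low-variability one. Per-bin counts are
#'   `n_high = round(quota * high / (high + low))` (half away from zero)
#'   and `n_low = quota - n_high`, so 27/25/20 give 18+9, 17+8, 13+7.
#' @param rank_combination How the variance and entropy orderings are
#'   combined into one score within each bin:
#'   `"mean-percentile-rank"` (default) averages the two within-bin
#'   percentile ranks — symmetric and scale-free; `"union-top-k"` orders
#'   ROIs by the better (smaller) of their two ranks, equivalent to
#'   growing the union of the top-k-by-variance and top-k-by-entropy
#'   sets. The two modes agree whenever the orderings coincide.
#' @param seed Integer seed for the batch split (see [split_batches()]).
#' @param total_target Expected total; must equal `sum(per_bin_quota)`.
#' @return Object of class `"selection_config"`.
#' @export
selection_config <- function(per_bin_quota = c(LE10 = 27, GT10_LE40 = 25, GT40 = 20),
                             high_low_ratio = c(2, 1),
                             rank_combination = c("mean-percentile-rank", "union-top-k"),
                             seed = 1L,
                             total_target = sum(per_bin_quota)) {
  rank_combination <- match.arg(rank_combination)
  if (is.null(names(per_bin_quota))) names(per_bin_quota) <- density_bins()
  if (!setequal(names(per_bin_quota), density_bins())) {
    stop("per_bin_quota must be named by density_bins()", call. = FALSE)
  }
  per_bin_quota <- per_bin_quota[density_bins()]
  if (any(per_bin_quota < 0) || sum(per_bin_quota) < 1) {
    stop("per-bin quotas must be non-negative with a positive total", call. = FALSE)
  }
  if (length(high_low_ratio) != 2 || any(high_low_ratio <= 0)) {
    stop("high_low_ratio must be two positive numbers", call. = FALSE)
  }
  if (sum(per_bin_quota) != total_target) {
    stop(
      "per_bin_quota sums to ", sum(per_bin_quota),
      " but total_target is ", total_target,
      call. = FALSE
    )
  }
  structure(
    list(
      per_bin_quota = per_bin_quota,
      high_low_ratio = high_low_ratio,
      rank_combination = rank_combination,
      seed = as.integer(seed),
      total_target = total_target
    ),
    class = "selection_config"
  )
}

#' @export
print.selection_config <- function(x, ...) {
  cat("Selection configuration\n")
  cat("  quotas: ", paste(names(x$per_bin_quota), x$per_bin_quota, sep = "=", collapse = ", "), "\n")
  cat("  high:low ratio ", x$high_low_ratio[1], ":", x$high_low_ratio[2],
      ", ranking by ", x$rank_combination, ", seed ", x$seed, "\n", sep = "")
  invisible(x)
}

# round-half-away-from-zero; base round() is round-half-even
round_half_up <- function(x) floor(x + 0.5)

split_quota <- function(quota, ratio) {
  n_high <- round_half_up(quota * ratio[1] / sum(ratio))
  c(high = n_high, low = quota - n_high)
}

#' Keep only ROIs whose density variance is calculable
#'
#' An ROI needs at least two density scores for a sample variance; ROIs
#' scored once or never (e.g. labelled exclusively with non-evaluable
#' labels) are removed before selection. Row order is preserved.
#'
#' @param aggregates Tibble from [aggregate_rois()].
#' @return The subset with `sample_variance` present.
#' @export
filter_variance_calculable <- function(aggregates) {
  dplyr::filter(aggregates, !is.na(.data$sample_variance))
}

# Within-bin composite ordering. Returns the aggregates with a
# composite_rank column: larger = more extreme in the "high" direction.
composite_score <- function(bin_df, mode) {
  n <- nrow(bin_df)
  pr_var <- rank(bin_df$sample_variance, ties.method = "average") / n
  pr_ent <- rank(bin_df$entropy, ties.method = "average") / n
  if (mode == "mean-percentile-rank") {
    (pr_var + pr_ent) / 2
  } else {
    # best (largest) of the two percentile ranks: sorting descending on
    # this equals growing the union of top-k-by-variance / top-k-by-entropy
    pmax(pr_var, pr_ent)
  }
}

#' Stratified selection of extreme-variability ROIs
#'
#' Within each infiltration bin, ROIs are scored by a combination of
#' their density-variance and label-entropy ranks (see
#' [selection_config()]); the top `n_high` and bottom `n_low` are
#' selected, with `n_high:n_low` matching the configured ratio. Ties are
#' broken lexicographically by (variance, entropy, roi_id), so the
#' selection is deterministic and invariant to the input row order.
#'
#' @param aggregates Variance-filtered tibble from
#'   [filter_variance_calculable()]; every row must have a density bin.
#' @param config A [selection_config()].
#' @return Object of class `"stils_selection"`: a list with `entries`
#'   (tibble: `roi_id`, `density_bin`, `stratum`, `composite_rank`;
#'   `batch` is `NA` until [split_batches()]) and the `config` used.
#' @examples
#' cohort <- simulate_cohort(synthetic_config(n_rois = 200, seed = 7))
#' agg <- filter_variance_calculable(aggregate_rois(cohort$crowd))
#' cfg <- selection_config(per_bin_quota = c(LE10 = 9, GT10_LE40 = 6, GT40 = 6))
#' stratified_select(agg, cfg)
#' @export
stratified_select <- function(aggregates, config = selection_config()) {
  if (!inherits(config, "selection_config")) {
    stop("config must be a selection_config()", call. = FALSE)
  }
  if (any(is.na(aggregates$sample_variance))) {
    stop("aggregates contain non-calculable variances; apply filter_variance_calculable() first",
         call. = FALSE)
  }
  if (anyDuplicated(aggregates$roi_id)) {
    stop("duplicate roi_id in aggregates", call. = FALSE)
  }

  # set semantics: canonical order before ranking, so input order is moot
  aggregates <- dplyr::arrange(aggregates, .data$roi_id)

  pick <- function(bin) {
    quota <- config$per_bin_quota[[bin]]
    if (quota == 0) return(NULL)
    bin_df <- aggregates[!is.na(aggregates$density_bin) & aggregates$density_bin == bin, ]
    if (nrow(bin_df) < quota) {
      stop(
        "bin ", bin, " holds ", nrow(bin_df),
        " variance-calculable ROIs but its quota is ", quota,
        call. = FALSE
      )
    }
    counts <- split_quota(quota, config$high_low_ratio)
    score <- composite_score(bin_df, config$rank_combination)
    ord_high <- order(-score, -bin_df$sample_variance, -bin_df$entropy, bin_df$roi_id)
    ord_low <- order(score, bin_df$sample_variance, bin_df$entropy, bin_df$roi_id)
    hi <- ord_high[seq_len(counts[["high"]])]
    lo <- ord_low[seq_len(counts[["low"]])]
    if (length(intersect(hi, lo)) > 0) {
      stop("bin ", bin, ": high and low strata overlap (bin too small for quota)", call. = FALSE)
    }
    tibble::tibble(
      roi_id = bin_df$roi_id[c(hi, lo)],
      density_bin = factor(bin, levels = density_bins()),
      stratum = rep(c("high", "low"), times = counts),
      composite_rank = score[c(hi, lo)]
    )
  }

  entries <- purrr::map(density_bins(), pick) |> dplyr::bind_rows()
  entries$batch <- NA_character_
  structure(list(entries = entries, config = config), class = "stils_selection")
}

#' Split a selection into two training batches
#'
#' Each (bin, stratum) cell is split as evenly as possible (cell sizes
#' differing by at most one) between Training Batch I — intended as a
#' training set for a test with feedback — and Training Batch II — a
#' proficiency test. The split is randomized but fully determined by the
#' seed.
#'
#' @param selection A `"stils_selection"` whose batch is not yet assigned.
#' @param seed Integer seed; defaults to the selection config's seed.
#' @return The selection with `entries$batch` filled in.
#' @export
split_batches <- function(selection, seed = selection$config$seed) {
  if (!inherits(selection, "stils_selection")) {
    stop("selection must come from stratified_select()", call. = FALSE)
  }
  if (any(!is.na(selection$entries$batch))) {
    stop("batches already assigned", call. = FALSE)
  }
  entries <- selection$entries
  withr::with_seed(seed, {
    imbalance <- 0L # (batch I) minus (batch II), to keep totals even too
    for (bin in levels(entries$density_bin)) {
      for (st in c("high", "low")) {
        idx <- which(entries$density_bin == bin & entries$stratum == st)
        if (length(idx) == 0) next
        extra <- 0L
        if (length(idx) %% 2 == 1) {
          # odd cell: the spare ROI goes to whichever batch is behind
          extra <- if (imbalance < 0) 1L else if (imbalance > 0) 0L else stats::rbinom(1, 1, 0.5)
          imbalance <- imbalance + if (extra == 1L) 1L else -1L
        }
        n1 <- floor(length(idx) / 2) + extra
        to_one <- sample(idx, n1)
        entries$batch[idx] <- "Training Batch II"
        entries$batch[to_one] <- "Training Batch I"
      }
    }
  })
  selection$entries <- entries
  selection
}

#' @export
print.stils_selection <- function(x, ...) {
  e <- x$entries
  cat("Stratified ROI selection: ", nrow(e), " ROIs (",
      sum(e$stratum == "high"), " high / ", sum(e$stratum == "low"), " low)\n", sep = "")
  tab <- table(e$density_bin, e$stratum)
  print(tab)
  if (all(!is.na(e$batch))) {
    cat("batches: ", paste(names(table(e$batch)), table(e$batch), sep = " = ", collapse = ", "), "\n")
  } else {
    cat("batches not yet assigned (see split_batches())\n")
  }
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a stratified selection
#'
#' @param x A `"stils_selection"`.
#' @param ... Unused.
#' @return The entries tibble: `roi_id`, `density_bin`, `stratum`,
#'   `composite_rank`, `batch`.
#' @method tidy stils_selection
#' @export
tidy.stils_selection <- function(x, ...) x$entries

#' One-row summary of a stratified selection
#'
#' @param x A `"stils_selection"`.
#' @param ... Unused.
#' @return Tibble with `n_selected`, `n_high`, `n_low`, per-bin counts,
#'   and the ranking mode.
#' @method glance stils_selection
#' @export
glance.stils_selection <- function(x, ...) {
  e <- x$entries
  bins <- table(e$density_bin)
  tibble::tibble(
    n_selected = nrow(e),
    n_high = sum(e$stratum == "high"),
    n_low = sum(e$stratum == "low"),
    n_le10 = as.integer(bins[["LE10"]]),
    n_gt10_le40 = as.integer(bins[["GT10_LE40"]]),
    n_gt40 = as.integer(bins[["GT40"]]),
    rank_combination = x$config$rank_combination
  )
}
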