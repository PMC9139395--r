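test_that("variance filter keeps exactly the ROIs with >= 2 density scores", {
  recs <- dplyr::bind_rows(
    make_records("A", c(ITS, ITS, IM), c(10, 20, 30)),
    make_records("B", c(ITS, IM), c(15, NA)),
    make_records("C", c(OR, TWNIS), c(NA, NA))
  )
  agg <- aggregate_rois(recs)
  kept <- filter_variance_calculable(agg)
  expect_identical(kept$roi_id, "A")
  expect_identical(filter_variance_calculable(kept), kept) # idempotent
})

test_that("default quotas and 2:1 ratio yield 72 ROIs as 18/9, 17/8, 13/7", {
  agg <- dplyr::bind_rows(
    make_bin_aggregates(40, "LE10", seed = 1),
    make_bin_aggregates(40, "GT10_LE40", seed = 2),
    make_bin_aggregates(40, "GT40", seed = 3)
  )
  sel <- stratified_select(agg, selection_config())
  e <- tidy(sel)
  expect_equal(nrow(e), 72)
  expect_equal(sum(e$stratum == "high"), 48)
  expect_equal(sum(e$stratum == "low"), 24)
  tab <- table(e$density_bin, e$stratum)
  expect_equal(unname(tab[, "high"]), c(18, 17, 13))
  expect_equal(unname(tab[, "low"]), c(9, 8, 7))
  expect_false(anyDuplicated(e$roi_id) > 0)
})

test_that("selection is deterministic and invariant to input row order and ties", {
  agg <- make_bin_aggregates(30, "LE10", seed = 5)
  # force exact ties in both statistics
  agg$sample_variance[3] <- agg$sample_variance[4]
  agg$entropy[3] <- agg$entropy[4]
  cfg <- selection_config(per_bin_quota = c(LE10 = 9, GT10_LE40 = 0, GT40 = 0))
  base <- tidy(stratified_select(agg, cfg))
  withr::with_seed(77, {
    for (i in 1:5) {
      shuffled <- agg[sample.int(nrow(agg)), ]
      expect_identical(tidy(stratified_select(shuffled, cfg)), base)
    }
  })
})

test_that("infeasible quotas and unfiltered input are refused", {
  agg <- make_bin_aggregates(10, "LE10", seed = 6)
  expect_error(
    stratified_select(agg, selection_config(per_bin_quota = c(LE10 = 11, GT10_LE40 = 0, GT40 = 0))),
    "quota"
  )
  agg$sample_variance[1] <- NA
  expect_error(
    stratified_select(agg, selection_config(per_bin_quota = c(LE10 = 5, GT10_LE40 = 0, GT40 = 0))),
    "filter_variance_calculable"
  )
  expect_error(
    selection_config(per_bin_quota = c(LE10 = 5, GT10_LE40 = 0, GT40 = 0), total_target = 10),
    "total_target"
  )
})

test_that("planted rank-dominating ROIs fill the high stratum", {
  agg <- make_bin_aggregates(30, "LE10", seed = 8)
  planted_ids <- sprintf("planted_%d", 1:5)
  planted <- tibble::tibble(
    roi_id = planted_ids,
    entropy = log(4) - 0.001 * (1:5),
    mean_density = 5,
    sample_variance = 5000 + 1:5,
    density_bin = factor("LE10", levels = density_bins())
  )
  cfg <- selection_config(per_bin_quota = c(LE10 = 6, GT10_LE40 = 0, GT40 = 0))
  e <- tidy(stratified_select(dplyr::bind_rows(agg, planted), cfg))
  high <- e$roi_id[e$stratum == "high"]
  expect_length(high, 4)
  expect_true(all(high %in% planted_ids))
})

test_that("raising the quota nests the previous selection within each stratum", {
  agg <- make_bin_aggregates(30, "LE10", seed = 9)
  pick <- function(q) {
    tidy(stratified_select(agg, selection_config(per_bin_quota = c(LE10 = q, GT10_LE40 = 0, GT40 = 0))))
  }
  prev <- pick(6)
  for (q in c(9, 12, 15, 18)) {
    cur <- pick(q)
    for (st in c("high", "low")) {
      expect_true(all(
        prev$roi_id[prev$stratum == st] %in% cur$roi_id[cur$stratum == st]
      ))
    }
    prev <- cur
  }
})

test_that("the two rank-combination modes agree when the orderings coincide", {
  withr::with_seed(10, {
    agg <- make_bin_aggregates(25, "GT40", seed = 11)
    # entropy made a monotone function of variance: identical orderings
    agg$entropy <- log(4) * rank(agg$sample_variance) / nrow(agg)
  })
  q <- c(LE10 = 0, GT10_LE40 = 0, GT40 = 12)
  a <- tidy(stratified_select(agg, selection_config(q, rank_combination = "mean-percentile-rank")))
  b <- tidy(stratified_select(agg, selection_config(q, rank_combination = "union-top-k")))
  expect_identical(a[c("roi_id", "stratum")], b[c("roi_id", "stratum")])
})

test_that("selected high-stratum variances dominate the unselected ones", {
  cohort <- simulate_cohort(synthetic_config(n_rois = 300, seed = 21))
  agg <- filter_variance_calculable(aggregate_rois(cohort$crowd))
  cfg <- selection_config(per_bin_quota = c(LE10 = 12, GT10_LE40 = 9, GT40 = 6))
  e <- tidy(stratified_select(agg, cfg))
  high <- agg$sample_variance[agg$roi_id %in% e$roi_id[e$stratum == "high"]]
  rest <- agg$sample_variance[!agg$roi_id %in% e$roi_id]
  # direction check only: one-sided rank comparison
  w <- stats::wilcox.test(high, rest, alternative = "greater", exact = FALSE)
  expect_gt(stats::median(high), stats::median(rest))
  expect_lt(w$p.value, 0.5)
})

test_that("batch split is even, stratified, seeded, and refuses reassignment", {
  agg <- dplyr::bind_rows(
    make_bin_aggregates(40, "LE10", seed = 12),
    make_bin_aggregates(40, "GT10_LE40", seed = 13),
    make_bin_aggregates(40, "GT40", seed = 14)
  )
  sel <- stratified_select(agg, selection_config())
  done <- split_batches(sel, seed = 99)
  e <- tidy(done)
  expect_equal(unname(table(e$batch)), c(36L, 36L), ignore_attr = TRUE)
  # every bin-stratum cell splits with at most one ROI of imbalance
  cells <- e |>
    dplyr::count(density_bin, stratum, batch) |>
    tidyr::pivot_wider(names_from = "batch", values_from = "n", values_fill = 0L)
  expect_true(all(abs(cells$`Training Batch I` - cells$`Training Batch II`) <= 1))
  # determinism and state protection
  expect_identical(tidy(split_batches(sel, seed = 99)), e)
  expect_error(split_batches(done, seed = 99), "already")
})

test_that("tidy and glance expose the selection in broom shapes", {
  agg <- dplyr::bind_rows(
    make_bin_aggregates(30, "LE10", seed = 15),
    make_bin_aggregates(30, "GT10_LE40", seed = 16),
    make_bin_aggregates(30, "GT40", seed = 17)
  )
  sel <- stratified_select(agg, selection_config())
  expect_named(tidy(sel), c("roi_id", "density_bin", "stratum", "composite_rank", "batch"))
  g <- glance(sel)
  expect_equal(g$n_selected, 72)
  expect_equal(g$n_high, 48)
  expect_equal(c(g$n_le10, g$n_gt10_le40, g$n_gt40), c(27L, 25L, 20L))
})
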