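noiseless_config <- function(n_rois = 80, seed = 1) {
  synthetic_config(
    n_rois = n_rois,
    density_noise_sd = c(crowd = 0, expert = 0),
    label_confusion = list(crowd = diag(4), expert = diag(4)),
    seed = seed
  )
}

test_that("the noiseless limit reproduces truth exactly", {
  cohort <- simulate_cohort(noiseless_config(seed = 2))
  truth <- cohort$truth
  for (arm in list(cohort$crowd, cohort$experts)) {
    joined <- dplyr::left_join(arm, truth, by = "roi_id")
    expect_identical(joined$roi_label, joined$true_label)
    expect_equal(joined$stils_density, joined$true_density)
  }
  agg <- aggregate_rois(cohort$experts)
  expect_true(all(agg$entropy == 0))
  expect_true(all(agg$sample_variance[!is.na(agg$sample_variance)] == 0))
  rec <- recovery_report(truth, agg)
  expect_equal(rec$bias, 0)
  expect_equal(rec$rmse, 0)
  expect_equal(rec$majority_accuracy, 100)
})

test_that("generated cohorts pass strict validation and are seed-deterministic", {
  cfg <- synthetic_config(n_rois = 150, seed = 5)
  cohort <- simulate_cohort(cfg)
  expect_silent(validate_annotations(cohort$crowd, strict = TRUE))
  expect_silent(validate_annotations(cohort$experts, strict = TRUE))
  # truth invariant: density absent iff label not evaluable
  expect_identical(
    is.na(cohort$truth$true_density),
    !label_is_evaluable(cohort$truth$true_label)
  )
  again <- simulate_cohort(synthetic_config(n_rois = 150, seed = 5))
  expect_identical(cohort$crowd, again$crowd)
  expect_identical(cohort$experts, again$experts)
  other <- simulate_cohort(synthetic_config(n_rois = 150, seed = 6))
  expect_false(identical(cohort$crowd, other$crowd))
})

test_that("experts disperse less than the crowd on a 500-ROI cohort", {
  cfg <- synthetic_config(
    n_rois = 500,
    density_noise_sd = c(crowd = 20, expert = 5),
    seed = 19
  )
  cohort <- simulate_cohort(cfg)
  crowd_var <- aggregate_rois(cohort$crowd)$sample_variance
  expert_var <- aggregate_rois(cohort$experts)$sample_variance
  expect_gt(
    stats::median(crowd_var, na.rm = TRUE),
    stats::median(expert_var, na.rm = TRUE)
  )
})

test_that("more density noise cannot lower the median per-ROI variance", {
  med_var <- function(sd) {
    cfg <- synthetic_config(
      n_rois = 200,
      density_noise_sd = c(crowd = sd, expert = 5),
      seed = 23
    )
    stats::median(aggregate_rois(simulate_cohort(cfg)$crowd)$sample_variance, na.rm = TRUE)
  }
  meds <- vapply(c(0, 5, 15, 30), med_var, numeric(1))
  expect_true(all(diff(meds) >= 0))
})

test_that("more label confusion cannot lower the median entropy", {
  med_ent <- function(diag_mass) {
    conf <- matrix((1 - diag_mass) / 3, 4, 4)
    diag(conf) <- diag_mass
    cfg <- synthetic_config(
      n_rois = 200,
      label_confusion = list(crowd = conf, expert = diag(4)),
      seed = 29
    )
    stats::median(aggregate_rois(simulate_cohort(cfg)$crowd)$entropy)
  }
  meds <- vapply(c(1, 0.9, 0.7, 0.5), med_ent, numeric(1))
  expect_true(all(diff(meds) >= 0))
})

test_that("uniform label confusion yields the multinomial entropy expectation", {
  uniform <- matrix(0.25, 4, 4)
  cfg <- synthetic_config(
    n_rois = 400,
    n_expert_readers = 12,
    label_confusion = list(crowd = uniform, expert = uniform),
    seed = 37
  )
  cohort <- simulate_cohort(cfg)
  agg <- aggregate_rois(cohort$experts) # complete design: 12 reads per ROI
  # oracle: mean entropy of multinomial(12, uniform over 4) label counts
  withr::with_seed(41, {
    sims <- replicate(4000, entropy_oracle(as.vector(stats::rmultinom(1, 12, rep(0.25, 4)))))
  })
  se <- stats::sd(agg$entropy) / sqrt(nrow(agg))
  expect_lt(abs(mean(agg$entropy) - mean(sims)), 3 * se + 3 * stats::sd(sims) / sqrt(length(sims)))
})

test_that("uniform confusion drives majority accuracy to chance", {
  uniform <- matrix(0.25, 4, 4)
  cfg <- synthetic_config(
    n_rois = 500,
    label_confusion = list(crowd = uniform, expert = uniform),
    seed = 43
  )
  cohort <- simulate_cohort(cfg)
  agg <- aggregate_rois(cohort$experts)
  rec <- recovery_report(cohort$truth, agg)
  # oracle: P(untied argmax of multinomial(6, uniform) hits one fixed label)
  withr::with_seed(47, {
    hit <- replicate(8000, {
      counts <- as.vector(stats::rmultinom(1, 6, rep(0.25, 4)))
      sum(counts == max(counts)) == 1 && which.max(counts) == 1
    })
  })
  p_chance <- mean(hit) * 100
  n_eval <- sum(label_is_evaluable(cohort$truth$true_label))
  tol <- 3 * sqrt(p_chance * (100 - p_chance) / n_eval) + 1
  expect_lt(abs(rec$majority_accuracy - p_chance), tol)
})

test_that("unbiased reader noise leaves the pooled mean nearly unbiased", {
  cfg <- synthetic_config(
    n_rois = 300,
    density_noise_sd = c(crowd = 10, expert = 10),
    reads_per_roi_crowd = 20,
    n_crowd_readers = 29,
    seed = 53
  )
  cohort <- simulate_cohort(cfg)
  rec <- recovery_report(cohort$truth, aggregate_rois(cohort$crowd))
  expect_lt(abs(rec$bias), 1)
})

test_that("recovery_report rejects aggregates with unknown ROIs", {
  cohort <- simulate_cohort(noiseless_config(n_rois = 20, seed = 3))
  agg <- aggregate_rois(cohort$crowd)
  agg$roi_id[1] <- "intruder"
  expect_error(recovery_report(cohort$truth, agg), "absent from truth")
})
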