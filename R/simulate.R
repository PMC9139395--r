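# Synthetic multi-reader cohort generator with planted per-ROI truth.
#
# Emulates the structure of a crowd + expert-panel sTILs reader study:
# each ROI has a true tissue label and (when that label is evaluable) a
# true density; readers draw their label from a cohort-specific confusion
# row and, when their drawn label is evaluable, report the true density
# plus cohort noise clipped to [0, 100]. The crowd reads a random subset
# of ROIs per reader (incomplete design); the expert panel reads
# everything (complete design).

default_confusion <- function(diag) {
  m <- matrix((1 - diag) / 3, 4, 4, dimnames = list(roi_labels(), roi_labels()))
  diag(m) <- diag
  m
}

#' Synthetic cohort configuration
#'
#' Defaults emulate a pilot crowd study of 640 ROIs read by 29 crowd
#' pathologists (about 11.5 reads per ROI on average, an incomplete
#' design) followed by a 6-member expert panel reading every ROI, with
#' the expert cohort both less label-confused and less density-dispersed
#' than the crowd.
#'
#' @param n_rois Number of ROIs. Default 640.
#' @param bin_mixture Named proportions of evaluable-truth ROIs per
#'   infiltration bin; default 385:152:33 (normalized), the observed
#'   low/moderate/high split of a pilot cohort.
#' @param true_label_probs Named probabilities over [roi_labels()] for the
#'   ROI's true tissue label. Default heavily favours Intra-Tumoral
#'   Stroma with a sizeable Other Regions minority, matching observed
#'   majority-label frequencies.
#' @param n_crowd_readers,n_expert_readers Cohort sizes. Defaults 29, 6.
#' @param reads_per_roi_crowd Mean crowd reads per ROI; each ROI's reader
#'   subset is Binomial(`n_crowd_readers`, `reads_per_roi_crowd /
#'   n_crowd_readers`)-sized, so a few ROIs get fewer than two scores,
#'   mirroring the variance-calculability attrition of real incomplete
#'   designs. Default 11.52 (7373 estimates / 640 ROIs).
#' @param density_noise_sd Named per-cohort reader noise sd on the density
#'   scale, crowd noisier than experts. Default `c(crowd = 20, expert = 5)`,
#'   interpreted at a density of 50 when `density_noise_model = "sqrt"`.
#' @param density_noise_model `"sqrt"` (default): a reader's noise sd at
#'   latent density d is `density_noise_sd * sqrt(max(d, 5) / 50)`, so
#'   dispersion grows with infiltration, as observed in reader studies,
#'   and near-zero densities are not smeared across bins by clipping;
#'   `"constant"`: the sd is used as-is at every density (convenient for
#'   closed-form checks).
#' @param label_confusion Named list of two row-stochastic 4x4 matrices
#'   (`crowd`, `expert`) over [roi_labels()]: row = true label, column =
#'   reported label. Defaults: uniform off-diagonal with diagonal 0.70
#'   (crowd) and 0.94 (expert).
#' @param seed Integer seed; the whole generated cohort is a deterministic
#'   function of the configuration.
#' @return Object of class `"synthetic_config"`.
#' @export
synthetic_config <- function(n_rois = 640,
                             bin_mixture = c(LE10 = 385, GT10_LE40 = 152, GT40 = 33),
                             true_label_probs = c(
                               "Intra-Tumoral Stroma" = 0.82,
                               "Invasive Margin" = 0.03,
                               "Tumor with No Intervening Stroma" = 0.03,
                               "Other Regions" = 0.12
                             ),
                             n_crowd_readers = 29,
                             n_expert_readers = 6,
                             reads_per_roi_crowd = 7373 / 640,
                             density_noise_sd = c(crowd = 20, expert = 5),
                             density_noise_model = c("sqrt", "constant"),
                             label_confusion = list(
                               crowd = default_confusion(0.70),
                               expert = default_confusion(0.94)
                             ),
                             seed = 1L) {
  if (n_rois < 1) stop("n_rois must be positive", call. = FALSE)
  if (!setequal(names(bin_mixture), density_bins())) {
    stop("bin_mixture must be named by density_bins()", call. = FALSE)
  }
  bin_mixture <- bin_mixture[density_bins()] / sum(bin_mixture)
  if (!setequal(names(true_label_probs), roi_labels())) {
    stop("true_label_probs must be named by roi_labels()", call. = FALSE)
  }
  true_label_probs <- true_label_probs[roi_labels()] / sum(true_label_probs)
  density_noise_model <- match.arg(density_noise_model)
  if (any(density_noise_sd < 0)) stop("density_noise_sd must be non-negative", call. = FALSE)
  for (cohort in c("crowd", "expert")) {
    m <- label_confusion[[cohort]]
    if (is.null(m) || !is.matrix(m) || any(dim(m) != 4) || any(m < 0) ||
        any(abs(rowSums(m) - 1) > 1e-8)) {
      stop("label_confusion$", cohort, " must be a row-stochastic 4x4 matrix", call. = FALSE)
    }
  }
  if (reads_per_roi_crowd <= 0 || reads_per_roi_crowd > n_crowd_readers) {
    stop("reads_per_roi_crowd must lie in (0, n_crowd_readers]", call. = FALSE)
  }
  structure(
    list(
      n_rois = as.integer(n_rois),
      bin_mixture = bin_mixture,
      true_label_probs = true_label_probs,
      n_crowd_readers = as.integer(n_crowd_readers),
      n_expert_readers = as.integer(n_expert_readers),
      reads_per_roi_crowd = reads_per_roi_crowd,
      density_noise_sd = density_noise_sd,
      density_noise_model = density_noise_model,
      label_confusion = label_confusion,
      seed = as.integer(seed)
    ),
    class = "synthetic_config"
  )
}

bin_range <- function(bin) {
  switch(bin,
    LE10 = c(0, 10),
    GT10_LE40 = c(10, 40),
    GT40 = c(40, 100)
  )
}

#' Generate a synthetic crowd + expert multi-reader cohort
#'
#' Draws per-ROI truth (label, and density when the label is evaluable),
#' then simulates each cohort's annotations: the reported label comes
#' from the cohort's confusion row of the true label; a density is
#' reported only under an evaluable drawn label, as the true density plus
#' Gaussian cohort noise clipped to \[0, 100\]. For an ROI whose truth is
#' non-evaluable, a reader who nevertheless calls it evaluable scores
#' around a latent density of zero. Generated annotations always satisfy
#' strict validation: no density is ever paired with a non-evaluable
#' label.
#'
#' @param config A [synthetic_config()].
#' @return List of class `"stils_cohort"`: `crowd` and `experts`
#'   annotation tibbles (columns as in [read_annotations()]) and `truth`
#'   (`roi_id`, `true_label`, `true_density`).
#' @examples
#' cohort <- simulate_cohort(synthetic_config(n_rois = 50, seed = 3))
#' nrow(cohort$truth)
#' @export
simulate_cohort <- function(config = synthetic_config()) {
  if (!inherits(config, "synthetic_config")) {
    stop("config must come from synthetic_config()", call. = FALSE)
  }
  withr::with_seed(config$seed, {
    n <- config$n_rois
    roi_id <- sprintf("roi_%04d", seq_len(n))
    true_label <- sample(roi_labels(), n, replace = TRUE, prob = config$true_label_probs)
    evaluable <- true_label %in% roi_labels()[1:2]
    bins <- sample(density_bins(), n, replace = TRUE, prob = config$bin_mixture)
    lims <- vapply(bins, bin_range, numeric(2))
    true_density <- ifelse(evaluable, stats::runif(n, lims[1, ], lims[2, ]), NA_real_)
    truth <- tibble::tibble(roi_id = roi_id, true_label = true_label, true_density = true_density)

    read_one_cohort <- function(cohort_name, reader_ids, roi_reader_pairs) {
      m <- nrow(roi_reader_pairs)
      conf <- config$label_confusion[[cohort_name]]
      true_idx <- match(truth$true_label[roi_reader_pairs$roi], roi_labels())
      drawn <- vapply(
        true_idx,
        function(i) sample.int(4, 1, prob = conf[i, ]),
        integer(1)
      )
      drawn_label <- roi_labels()[drawn]
      drawn_eval <- drawn <= 2
      latent <- truth$true_density[roi_reader_pairs$roi]
      latent[is.na(latent)] <- 0 # misread non-evaluable tissue scores near zero
      sd_base <- config$density_noise_sd[[cohort_name]]
      sd_eff <- if (config$density_noise_model == "sqrt") {
        sd_base * sqrt(pmax(latent, 5) / 50)
      } else {
        rep(sd_base, m)
      }
      noise <- stats::rnorm(m, 0, sd_eff)
      dens <- pmin(pmax(latent + noise, 0), 100)
      dens[!drawn_eval] <- NA_real_
      # percent stroma: a coarse companion estimate, high for stromal
      # tissue, near zero for non-evaluable calls
      stroma <- ifelse(drawn_eval,
        pmin(pmax(60 + stats::rnorm(m, 0, 15), 1), 100),
        NA_real_
      )
      tibble::tibble(
        roi_id = truth$roi_id[roi_reader_pairs$roi],
        reader_id = reader_ids[roi_reader_pairs$reader],
        cohort = if (cohort_name == "crowd") "crowd" else "expert",
        roi_label = drawn_label,
        percent_stroma = stroma,
        stils_density = dens
      )
    }

    # incomplete crowd design: per-ROI Binomial-sized reader subset
    p_read <- config$reads_per_roi_crowd / config$n_crowd_readers
    crowd_sizes <- stats::rbinom(n, config$n_crowd_readers, p_read)
    crowd_pairs <- purrr::map2(seq_len(n), crowd_sizes, function(i, k) {
      if (k == 0) return(NULL)
      tibble::tibble(roi = i, reader = sample.int(config$n_crowd_readers, k))
    }) |> dplyr::bind_rows()
    crowd <- read_one_cohort(
      "crowd",
      sprintf("crowd_%02d", seq_len(config$n_crowd_readers)),
      crowd_pairs
    )

    # complete expert design: every expert reads every ROI
    expert_pairs <- tidyr::expand_grid(
      roi = seq_len(n),
      reader = seq_len(config$n_expert_readers)
    )
    experts <- read_one_cohort(
      "expert",
      sprintf("expert_%d", seq_len(config$n_expert_readers)),
      expert_pairs
    )

    structure(
      list(crowd = crowd, experts = experts, truth = truth),
      class = "stils_cohort"
    )
  })
}

#' @export
print.stils_cohort <- function(x, ...) {
  cat("Synthetic sTILs reader cohort\n")
  cat("  ", nrow(x$truth), " ROIs; ",
      nrow(x$crowd), " crowd annotations (",
      dplyr::n_distinct(x$crowd$reader_id), " readers); ",
      nrow(x$experts), " expert annotations (",
      dplyr::n_distinct(x$experts$reader_id), " readers)\n", sep = "")
  invisible(x)
}

#' Recovery of planted truth by the aggregation pipeline
#'
#' Compares per-ROI aggregates against the generator's planted truth over
#' the evaluable-truth ROIs: bias and RMSE of the pooled mean density
#' against the true density, and the fraction of ROIs whose (untied)
#' majority label equals the true label.
#'
#' @param truth Truth tibble from [simulate_cohort()].
#' @param aggregates Tibble from [aggregate_rois()] on the same cohort's
#'   annotations.
#' @return One-row tibble: `n` (evaluable-truth ROIs with a pooled mean),
#'   `bias`, `rmse`, `majority_accuracy` (in percent; ties count as
#'   misses).
#' @export
recovery_report <- function(truth, aggregates) {
  extra <- setdiff(aggregates$roi_id, truth$roi_id)
  if (length(extra) > 0) {
    stop("aggregates contain roi_ids absent from truth: ",
         paste(utils::head(extra, 5), collapse = ", "), call. = FALSE)
  }
  joined <- truth |>
    dplyr::filter(label_is_evaluable(.data$true_label)) |>
    dplyr::inner_join(aggregates, by = "roi_id")
  with_mean <- dplyr::filter(joined, !is.na(.data$mean_density))
  err <- with_mean$mean_density - with_mean$true_density
  tibble::tibble(
    n = nrow(with_mean),
    bias = mean(err),
    rmse = sqrt(mean(err^2)),
    majority_accuracy = mean(joined$majority_label == joined$true_label) * 100
  )
}
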