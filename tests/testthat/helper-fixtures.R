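# Shared fixtures and independent oracles, built in code.

ITS <- "Intra-Tumoral Stroma"
IM <- "Invasive Margin"
TWNIS <- "Tumor with No Intervening Stroma"
OR <- "Other Regions"

# A small, clean annotation table.
make_records <- function(roi_id = "r1",
                         labels = c(ITS, ITS, IM),
                         densities = c(10, 20, 30),
                         cohort = "crowd") {
  tibble::tibble(
    roi_id = roi_id,
    reader_id = sprintf("reader_%02d", seq_along(labels)),
    cohort = cohort,
    roi_label = labels,
    percent_stroma = 50,
    stils_density = densities
  )
}

# Direct entropy computation, written independently of label_entropy():
# explicit loop over nonzero categories.
entropy_oracle <- function(counts) {
  total <- sum(counts)
  h <- 0
  for (k in counts) {
    if (k > 0) {
      p <- k / total
      h <- h - p * log(p)
    }
  }
  h
}

# All compositions of n into k non-negative parts.
compositions <- function(n, k) {
  if (k == 1) return(matrix(n, 1, 1))
  out <- list()
  for (first in 0:n) {
    rest <- compositions(n - first, k - 1)
    out[[length(out) + 1]] <- cbind(first, rest)
  }
  do.call(rbind, out)
}

# Two-pass sum-of-squares sample variance.
variance_oracle <- function(x) {
  m <- sum(x) / length(x)
  ss <- 0
  for (v in x) ss <- ss + (v - m)^2
  ss / (length(x) - 1)
}

# Type-7 quantile by hand: h = (n-1)p + 1, linear interpolation.
quantile_oracle <- function(x, p) {
  s <- sort(x)
  n <- length(s)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  s[lo] + (h - lo) * (s[hi] - s[lo])
}

# Random one-bin aggregates table for selection tests.
make_bin_aggregates <- function(n, bin = "LE10", seed = 1) {
  withr::with_seed(seed, {
    mean_density <- switch(bin,
      LE10 = runif(n, 0, 10),
      GT10_LE40 = runif(n, 10.001, 40),
      GT40 = runif(n, 40.001, 100)
    )
    tibble::tibble(
      roi_id = sprintf("%s_%03d", bin, seq_len(n)),
      entropy = runif(n, 0, log(4)),
      mean_density = mean_density,
      sample_variance = rexp(n, 1 / 100),
      density_bin = factor(bin, levels = density_bins())
    )
  })
}

# Replace every crowd record of the chosen ROIs with an extreme
# high-variance, high-entropy read set whose pooled mean stays inside the
# ROI's current bin: 4 reads each of three labels, densities only under
# the 8 evaluable reads.
plant_extremes <- function(crowd, roi_ids, bin) {
  scores <- switch(bin,
    LE10 = c(0, 0, 0, 0, 0, 0, 0, 80), # mean 10, variance 800
    GT10_LE40 = c(0, 0, 0, 0, 80, 80, 80, 80), # mean 40, variance ~1829
    GT40 = c(0, 0, 100, 100, 100, 100, 100, 100) # mean 75, variance ~2143
  )
  planted <- purrr::map(roi_ids, function(id) {
    tibble::tibble(
      roi_id = id,
      reader_id = sprintf("crowd_%02d", 1:12),
      cohort = "crowd",
      roi_label = rep(c(ITS, IM, TWNIS), each = 4),
      percent_stroma = c(rep(60, 8), rep(NA, 4)),
      stils_density = c(scores, rep(NA, 4))
    )
  }) |> dplyr::bind_rows()
  dplyr::bind_rows(
    dplyr::filter(crowd, !(roi_id %in% roi_ids)),
    planted
  )
}
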