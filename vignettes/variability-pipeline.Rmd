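---
title: "Quantifying and triaging inter-reader variability in sTILs annotations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying and triaging inter-reader variability in sTILs annotations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stilsvar)
library(dplyr)
```

## The problem

Stromal tumor-infiltrating lymphocytes (sTILs) are a prognostic biomarker
in breast cancer, scored by pathologists as the percentage of
tumor-associated stroma occupied by lymphocytes and plasma cells within a
region of interest (ROI) of an H&E-stained biopsy slide. Reference
("truth") annotations for validating sTILs-scoring algorithms are built
from many readers' scores, and those readers disagree — about what the
tissue is, and about how dense the infiltrate is. This package quantifies
that disagreement per ROI, selects the ROIs where disagreement is most
and least severe for expert review, and compares reader cohorts.

Each annotation record carries three data elements:

* an **ROI label**, one of four tissue categories. "Intra-Tumoral
  Stroma" and "Invasive Margin" contain tumor-associated stroma, so an
  sTILs density is defined there ("evaluable"); "Tumor with No
  Intervening Stroma" and "Other Regions" contain none, so no density can
  exist there ("not evaluable");
* a **percent tumor-associated stroma**: stroma area over total ROI area,
  times 100;
* an **sTILs density**: TILs area over stroma area, times 100.

Both percentages are continuous on [0, 100]. The density is undefined —
not zero — when there is no tumor-associated stroma, which is why
`compute_stils_density()` errors on a zero stroma area and why, in a
clean dataset, a density never accompanies a non-evaluable label.
Validation (`validate_annotations()`) enforces this *evaluability rule*
strictly for newly generated data; for historical pilot data, which
predate its enforcement, lenient mode retains such rows and flags them in
the report instead. Flagged densities are included in the pooled mean and
variance by default (`aggregate_rois(evaluable_densities_only = FALSE)`),
because pilot-era summary statistics were computed that way; the switch
exists because either convention is defensible and the raw data do not
always say which was used.

## Per-ROI statistics

For each ROI we pool all readers:

* **Label entropy** $H = -\sum_{i=1}^{4} p_i \ln p_i$, where $p_i$ is the
  fraction of readers choosing label $i$ — a variance analogue for
  categorical data. $H = 0$ exactly at unanimity; $H = \ln 4 \approx
  1.386$ at a uniform four-way split. The natural logarithm is the
  package default (a two-way 2:4 split prints as 0.64, a three-way even
  split as $\ln 3 \approx 1.1$); the base is configurable in
  `label_entropy()`.
* **Mean density** over the scores present, and the **unbiased sample
  variance** (denominator $n-1$; three scores of 0, 90, 90 give exactly
  2700). At least two scores are required — with fewer, the variance is
  *absent*, never zero.
* The **majority label**: all modal labels, ties kept and rendered joined
  by `" *AND* "` in canonical label order.
* A **density bin** from the mean: low ($\le 10\%$), moderate
  ($>10$–$40\%$), high ($>40\%$) infiltration, thresholds chosen as
  clinically meaningful management cut-points. Boundaries are closed on
  the right (a mean of exactly 10 is low), and a mean of 0 is placed in
  the low bin — "10% or less" includes zero even though the bins
  nominally partition $(0, 100]$.

```{r example}
recs <- tibble::tibble(
  roi_id = "example", reader_id = as.character(1:6), cohort = "crowd",
  roi_label = c("Invasive Margin", rep("Intra-Tumoral Stroma", 3),
                rep("Tumor with No Intervening Stroma", 2)),
  percent_stroma = 50,
  stils_density = c(0, 0, 0, 40, NA, NA)
)
aggregate_roi(recs) |>
  select(roi_id, entropy, majority_label, mean_density, sample_variance, density_bin)
```

## Stratified selection of extreme ROIs

To build training and proficiency material, the ROIs where readers
disagree most (and, as controls, least) are selected for expert review:

1. ROIs without a calculable variance are dropped
   (`filter_variance_calculable()`).
2. Survivors are stratified by density bin with per-bin quotas
   (default 27 / 25 / 20, total 72).
3. Within each bin, ROIs are ranked jointly on variance and entropy and
   the top/bottom are taken at a 2:1 high:low ratio:
   $n_\text{high} = \operatorname{round}(2q/3)$, giving 18+9, 17+8,
   13+7 for the default quotas (48 high, 24 low).
4. The selection is split evenly per (bin × stratum) cell into Training
   Batch I (test with feedback) and Training Batch II (proficiency
   test), randomized by seed.

**Combining "variance and entropy".** How the two orderings are merged
into one is a genuinely open design choice; the package ships two
explicit interpretations. The default, *mean percentile rank*, averages
each ROI's within-bin percentile ranks of variance and entropy: it is
symmetric in the two statistics and invariant to their scales. The
alternative, *union top-k*, orders ROIs by the better of their two ranks,
which equals growing the union of the top-$k$-by-variance and
top-$k$-by-entropy sets until the stratum fills. The modes coincide
whenever the two orderings agree, and both are deterministic: ties are
broken lexicographically by (variance, entropy, ROI id), so rerunning the
selection on a permuted input yields byte-identical results. Neither mode
claims to reproduce any particular historical selection's ROI
identities; the selection *counts* and the extremeness direction are the
reproducible contract.

Batch sizes are likewise not dictated by the statistics, so the package
chooses the most even stratified random split (cells differ by at most
one ROI, overall batches by at most one; with the default 72 ROIs the
split is exactly 36 + 36).

## Cohort comparison

`summarize_statistic()` produces median (IQR) cells of variance or
entropy per cohort view (all ROIs, selected ROIs, expert panel) — one
all-densities cell that pools across bins plus one cell per bin.
When cohorts are compared on the same ROIs, all views are stratified by
the *crowd's* mean-density bin (`bins =` argument), so a cell compares
the same ROIs under each view. Quartiles use linear interpolation
between order statistics (`stats::quantile` type 7), the mainstream
numerics default; the convention is configurable because published
tables rarely state theirs, and reproduction of third-party IQRs should
be judged to a tolerance. `paired_deltas()` matches the two cohorts per
ROI and reports expert-minus-crowd differences, with the expert value
absent where the expert side has no calculable statistic.
`majority_label_frequencies()` tabulates the rendered majority labels.
ROIs with no mean density are placed only in the all-densities cell,
since they have no bin.

## The synthetic cohort generator

`simulate_cohort()` exists so the full pipeline — ingestion, strict
validation, aggregation, filtering, selection, comparison — can be
exercised and tested without reader-study data. It emulates:

* **a crowd arm**: 29 readers, each ROI read by a Binomial(29, p) subset
  with mean ≈ 11.5 reads per ROI (640 ROIs × 11.5 ≈ the ~7400 estimates
  of a realistic pilot), so a few ROIs end up with fewer than two scores
  and are lost to the variance filter, as in real incomplete designs;
* **an expert arm**: 6 readers, complete design;
* **planted truth**: each ROI has a true label (defaults ≈ 82%
  Intra-Tumoral Stroma, 12% Other Regions, 3% each for the remaining
  two, matching observed majority-label frequencies) and, when that
  label is evaluable, a true density drawn within a bin from the default
  385:152:33 low:moderate:high mixture;
* **label confusion**: each reader's label is drawn from a
  cohort-specific row-stochastic confusion matrix (defaults: diagonal
  0.70 for the crowd, 0.94 for experts, uniform off-diagonal);
* **density noise**: a density is emitted only under an evaluable drawn
  label, as truth plus Gaussian noise clipped to [0, 100]. The
  per-cohort sd (defaults 20 crowd, 5 experts) is specified at a density
  of 50 and scaled by $\sqrt{d/50}$ (floored at $d = 5$), because
  reader dispersion in density scoring grows with the infiltration
  level — with this scaling the per-bin variance medians of a default
  cohort increase across bins roughly 25 / 130 / 300, the qualitative
  pattern seen in real crowd data, and near-zero truths are not smeared
  into higher bins by clipping. A constant-sd mode is available for
  closed-form checks. When a reader mislabels a truly non-evaluable ROI
  as evaluable, their score is drawn around a latent density of zero —
  the tissue contains nothing to score, but the record must still carry
  a density to be realistic.

Everything is a deterministic function of the seed.

What the generator does **not** model: per-reader bias or experience
effects, correlation between a reader's label and density errors,
image-driven difficulty (the pitfalls that make particular ROIs hard),
or the discuss-then-score dynamics of an expert panel. Tests that pass
on synthetic cohorts therefore demonstrate that the *pipeline machinery*
is correct and that directional contrasts (experts less dispersed than
crowd; selected ROIs more variable than unselected) follow from the
planted structure — they do not certify the magnitudes any real reader
population would produce. `recovery_report()` closes the loop by
checking the pipeline recovers the planted truth (bias and RMSE of the
pooled mean, majority-label accuracy) over evaluable-truth ROIs.

```{r pipeline}
cohort <- simulate_cohort(synthetic_config(n_rois = 300, seed = 42))
agg <- aggregate_rois(cohort$crowd)
recovery_report(cohort$truth, agg)

sel <- filter_variance_calculable(agg) |>
  stratified_select(selection_config(per_bin_quota = c(LE10 = 12, GT10_LE40 = 9, GT40 = 6))) |>
  split_batches(seed = 42)
glance(sel)
```

```{r compare}
expert_agg <- aggregate_rois(semi_join(cohort$experts, tidy(sel), by = "roi_id"))
crowd_select <- semi_join(agg, tidy(sel), by = "roi_id")
bins <- agg[c("roi_id", "density_bin")]
bind_rows(
  summarize_statistic(agg, "sample_variance", "Crowd-All", bins = bins),
  summarize_statistic(crowd_select, "sample_variance", "Crowd-Select", bins = bins),
  summarize_statistic(expert_agg, "sample_variance", "Experts", bins = bins)
) |> format_summary()
```

## Numerical and design choices

* **Entropy**: natural log by default; $0 \cdot \ln 0$ terms contribute
  0; an all-zero count vector is an error (an ROI with no annotations
  has no entropy), as is an empty score vector for the mean.
* **Variance**: $n - 1$ denominator, absent (not 0) below two scores.
* **Rounding for display**: comparisons against printed tables round
  half away from zero at the printed precision; internal computation is
  never rounded.
* **Bin edges**: right-closed; mean 0 → low bin.
* **Quota arithmetic**: $n_\text{high}$ rounds half away from zero so
  the 2:1 ratio gives the expected 18/17/13 at quotas 27/25/20; a
  per-bin quota of 0 skips the bin.
* **Determinism**: every stochastic step (generator, batch split) runs
  under `withr::with_seed`; selection itself is deterministic with
  explicit tie-breaks.
* **Degenerate inputs**: empty bins below quota raise an error naming
  the bin; an expert ROI absent from the crowd side is an integrity
  error; re-splitting batches is a state error.

Problem sizes in the test suite (cohorts of 150–640 ROIs, exhaustive
composition checks up to 8 readers) were chosen to make the statistical
checks stable at comfortable margins while keeping the suite quick to
run routinely.

## Limitations

The package reproduces a *procedure*, not a dataset: with real pilot
annotations as CSV input it will recompute per-ROI statistics, the
570-of-640-style variance filter, and the summary tables, but the exact
identities of historically selected ROIs depend on an unpublished rank
combination and cannot be guaranteed by either shipped mode. IQR
reproduction across software depends on the quantile convention.
No inter-reader agreement coefficients (ICC, kappa) and no inferential
tests of cohort differences are provided — the crowd-vs-expert
comparison is observational by design.
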