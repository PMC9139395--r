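# stilsvar

Inter-reader variability analysis for stromal tumor-infiltrating
lymphocyte (sTILs) annotations.

When many pathologists score the same regions of interest (ROIs) on
breast-biopsy slides — to build a reference dataset for validating
sTILs-scoring algorithms — they disagree, both about what the tissue is
and about how dense the lymphocytic infiltrate is. `stilsvar` turns a
table of per-(ROI, reader) annotation records into per-ROI disagreement
statistics, triages the ROIs where disagreement is extreme for expert
review, and compares reader cohorts. A seeded synthetic-cohort generator
with planted truth makes the whole pipeline testable without any reader
study.

Each record holds three data elements: a four-category **ROI label**
("Intra-Tumoral Stroma" and "Invasive Margin" are evaluable for sTILs;
"Tumor with No Intervening Stroma" and "Other Regions" are not, so no
density exists there), a **percent tumor-associated stroma**
(stroma area / ROI area × 100), and an **sTILs density**
(TILs area / stroma area × 100).

Per ROI, readers are pooled into:

- **label entropy** — Shannon entropy of the reader-label distribution,
  H = −Σᵢ pᵢ ln pᵢ over the four labels: 0 at unanimity, ln 4 at a
  uniform split;
- **mean** and **unbiased sample variance** (n − 1 denominator; scores
  0, 90, 90 give variance 2700) of the density scores, the variance
  absent below two scores;
- the tie-aware **majority label** (ties rendered joined by `" *AND* "`);
- a **density bin**: ≤ 10% (low), > 10–40% (moderate), > 40% (high)
  infiltration.

Selection then drops variance-less ROIs, ranks each bin jointly on
variance and entropy, draws the extremes at a 2:1 high:low ratio against
per-bin quotas (default 27/25/20 → 72 ROIs as 48 high + 24 low), and
splits them evenly into two training batches.

## Worked example

```r
library(stilsvar)
library(dplyr)

# one ROI, six readers: labels disagree, one density is an outlier
recs <- tibble::tibble(
  roi_id = "roi_42", reader_id = as.character(1:6), cohort = "crowd",
  roi_label = c("Invasive Margin", rep("Intra-Tumoral Stroma", 3),
                rep("Tumor with No Intervening Stroma", 2)),
  percent_stroma = 50,
  stils_density = c(0, 0, 0, 40, NA, NA)
)
aggregate_roi(recs) |>
  select(roi_id, entropy, majority_label, mean_density, sample_variance, density_bin)
#> # A tibble: 1 × 6
#>   roi_id entropy majority_label       mean_density sample_variance density_bin
#>   <chr>    <dbl> <chr>                       <dbl>           <dbl> <fct>
#> 1 roi_42    1.01 Intra-Tumoral Stroma           10             400 LE10
```

Three labels split 3/1/2 give entropy 1.01 nats; the four density scores
(the two non-evaluable readers score none) have mean 10 — just inside the
low-infiltration bin — and sample variance 400, driven by the lone 40.

On a full synthetic cohort (640 ROIs, 29 crowd readers, 6 experts):

```r
cohort <- simulate_cohort(synthetic_config(seed = 42))
agg  <- aggregate_rois(cohort$crowd)
calc <- filter_variance_calculable(agg)   # 610 of 640 ROIs keep a variance
sel  <- stratified_select(calc, selection_config()) |> split_batches(seed = 42)
sel
#> Stratified ROI selection: 72 ROIs (48 high / 24 low)
#>             high low
#>   LE10        18   9
#>   GT10_LE40   17   8
#>   GT40        13   7
#> batches:  Training Batch I = 36, Training Batch II = 36
```

Comparing density-variance across cohort views, stratified by the crowd's
density bin (median and interquartile range per cell):

```r
expert_agg   <- aggregate_rois(semi_join(cohort$experts, tidy(sel), by = "roi_id"))
crowd_select <- semi_join(agg, tidy(sel), by = "roi_id")
bins <- agg[c("roi_id", "density_bin")]
bind_rows(
  summarize_statistic(agg,          "sample_variance", "Crowd-All",    bins = bins),
  summarize_statistic(crowd_select, "sample_variance", "Crowd-Select", bins = bins),
  summarize_statistic(expert_agg,   "sample_variance", "Experts",      bins = bins)
) |> format_summary()
#>   view                  all                LE10             GT10_LE40                   GT40
#> 1 Crowd-All  36.75 (17.41–87.52) 22.73 (12.75–36.83) 108.18 (72.66–201.06) 353.21 (271.99–501.41)
#> 2 Crowd-Select 92.84 (44.44–288.21)  41.46 (5.73–50.50) 169.93 (52.24–240.26) 451.52 (262.69–601.94)
#> 3 Experts       5.90 (2.94–17.21)    2.69 (1.83–5.37)     9.43 (3.65–17.84)    19.36 (10.00–43.42)
```

The selected ROIs are more variable than the cohort at large, and the
(less noisy, less label-confused) expert arm is far less variable than
the crowd in every bin — the directional pattern the selection-and-review
workflow is designed around.

`run_pipeline()` executes validate → aggregate → filter → select →
compare in one call and writes every artifact plus a hashed
`manifest.json`; `inst/cli/stilsvar` wraps the same functions as
`validate` / `aggregate` / `select` / `compare` / `simulate` /
`reproduce` subcommands.

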