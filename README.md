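# dnbtip — dynamic network biomarker tipping-point analysis

Developmental processes often move through abrupt reorganizations: a
system lingers near one state, then crosses a critical threshold. Just
before such a transition, bifurcation theory predicts that a *dominant
group* of molecules — the dynamic network biomarker (DNB) — shows a
simultaneous surge in within-group correlation and variance together
with a collapse of its correlation to everything else. In a sliding
window over an age-ordered expression course, the composite index

```
CI = SD_d · PCC_d / PCC_o
```

(`SD_d`: mean standard deviation of the group's genes in the window;
`PCC_d`: mean |Pearson r| within the group; `PCC_o`: mean |Pearson r|
between the group and all other genes) peaks at the tipping point. The
motivating application is infant primate brain development, where
cortical gene expression reorganizes drastically within the first year
of life.

`dnbtip` is an R package for this analysis end to end:

* **data_io** — TSV/GEO-style matrix loading, per-sample rank-uniform
  normalization, per-gene standardization, age/species filtering;
* **dnb_core** — sliding windows, DNB statistics, a deterministic
  dominant-group search (max-CI dendrogram seed + eigengene-membership
  extension), CI trajectories, a multiplicity-calibrated peak test and
  an optional permutation test;
* **degs** — per-gene one-way ANOVA on log2 values, Benjamini–Hochberg
  FDR, direction-symmetric fold changes, DEG calling around the
  tipping point, gene-set overlaps;
* **exploratory** — sample clustering, PCA, classical-MDS age
  trajectory, first-year change fraction;
* **synthetic_data** — a latent-factor simulator that plants a known
  critical transition (plus DE genes) with full ground truth;
* **run_pipeline()** — the whole chain from files to a JSON report,
  with a thin CLI in `inst/scripts/dnb-pipeline.R`.

## Worked example

Simulate a 1000-gene course (10 periods × 3 samples, planted
transition at 0.2 years), scan it, and check the result against the
planted truth:

```r
library(dnbtip)

sim  <- generate_dataset(sim_config(seed = 1))
sim$dataset
#> ExpressionDataset: 1000 genes x 30 samples (raw)
#>   samples per species: synthetic=30
#>   age range: 0.05 - 0.5 years

scan <- dnb_scan(sim$dataset, window_size = 6, step = 3)
scan
#> DNB scan: 9 windows; tipping at window 3 (age 0.175 y), CI=4.721
#>   peak z = 2.88 -> NOT significant (threshold 3.42)
#>   DNB genes at tipping window: 61

evaluate_recovery(scan, sim$truth)
#> $hit
#> [1] TRUE
#> $window_offset
#> [1] 0
#> $jaccard
#> [1] 0.82
```

The scan localizes the planted transition exactly (window 3 spans ages
0.15–0.2 years, covering the planted tipping period at 0.2) and
recovers the 50-gene module at Jaccard 0.82. The top of the CI
trajectory shows the expected signature — variance and within-group
correlation up, outside correlation down:

```r
head(scan$scores[order(-scan$scores$ci), ], 3)
#>   window_index age_label group_size sd_d pcc_d pcc_o   ci
#> 3            3     0.175         61 1.91 0.970 0.392 4.72
#> 4            4     0.225         69 1.78 0.958 0.398 4.28
#> 2            2     0.125         10 1.08 0.899 0.330 2.94
```

(The conservative peak test withholds significance here: with only
nine windows, two of which straddle the transition, the leave-peak-out
z is compressed — see the methods vignette.)

Differential expression around the detected tipping age recovers the
40 planted DE genes:

```r
degs <- differential_expression(sim$dataset, split_age = scan$tipping_age)
table(degs$is_deg)
#> FALSE  TRUE
#>   960    40
```

From files, the same analysis is one call (or one shell command):

```r
run_pipeline(pipeline_config(
  matrix_path = "matrix.tsv", meta_path = "meta.tsv",
  out_dir = "results", species = "human", max_age = 1.0, seed = 1
))
```

which writes per-window score tables, DNB gene lists, DEG tables,
ordination coordinates and `report.json`.

## Documentation

The methods vignette (`vignettes/dnb-tipping-points.Rmd`) describes
the model and its assumptions, why the DNB statistics run on per-gene
standardized values while ordination runs on rank-uniform values, the
seed-and-extend dominant-group search, the calibration of the peak
test, the simulator's construction (with closed-form correlation
targets) and the known limitations of the method at small window
sizes.
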