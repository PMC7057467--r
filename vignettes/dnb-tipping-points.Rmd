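---
title: "Detecting developmental tipping points with dynamic network biomarkers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting developmental tipping points with dynamic network biomarkers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dnbtip)
```

## The model

Many biological processes do not drift smoothly from one state to the
next: they linger near a state, then cross a critical threshold and
reorganize abruptly. Bifurcation theory predicts a measurable signature
just before such a transition. As the dominant eigenvalue of the
system's Jacobian approaches criticality, one group of molecules — the
*dynamic network biomarker* (DNB), or dominant group — becomes governed
by the slowing critical mode. Three things happen to that group at
once:

1. the absolute Pearson correlations *within* the group surge,
2. its absolute correlations to *every other* molecule collapse,
3. the standard deviations of its members surge.

The three criteria combine into the composite index for a candidate
group $d$ within one time window:

$$ CI = \frac{SD_d \cdot PCC_d}{PCC_o} $$

where $SD_d$ is the mean standard deviation of the group's genes across
the window's samples, $PCC_d$ the mean absolute Pearson correlation
over pairs within the group, and $PCC_o$ the mean absolute correlation
between group members and all other genes. A sharp peak of $CI$ along a
time course marks the tipping point: the system is about to move.

`dnbtip` implements this analysis for age-ordered expression
time courses — the motivating application is infant primate brain
development, where cortical expression reorganizes drastically within
the first year of life — together with the surrounding pipeline:
loading and normalization, sliding windows, a dominant-group search,
peak significance, differential expression around the tipping point,
and exploratory ordination. A latent-factor simulator plants a known
transition so that every stage is testable against ground truth.

## Preprocessing: two transforms with two jobs

Two different transforms are used deliberately for different stages.

**Rank-uniform normalization** (`normalize_uniform()`) replaces each
sample's values by `rank / (G + 1)` with average ranks for ties. Every
sample then has the same uniform marginal on (0, 1), which removes
array-to-array intensity distortions and is the natural input for
sample-level clustering, PCA, and the MDS age trajectory. Ties receive
average ranks because that choice is deterministic and standard. The
raw matrix is always retained, because fold changes on rank scores are
meaningless.

**Per-gene standardization** (`standardize_genes()`) z-scores each gene
across the course and is applied internally by `dnb_scan()` before any
window statistic. Two reasons:

* $SD_d$ must compare genes on a common scale — on the raw scale it is
  dominated by whichever genes are highly expressed (multiplying a
  group by $k$ multiplies its $CI$ by $k$, a property the unit tests
  assert). After standardization a window's $SD_d$ is the share of each
  gene's course-wide variability realized in that window, which is
  exactly the "variance surge" the theory describes.
* Within-sample ranks must **not** be used for the correlation
  statistics. A rank is a function of *all* genes' values in the
  sample, so when a 5% module surges it mechanically displaces every
  mid-distribution gene's rank by about `n_module / G` — far above
  those genes' own rank jitter. This manufactures strong spurious
  anti-correlations between the module and the rest of the
  transcriptome, *raising* $PCC_o$ at the tipping point, exactly
  inverting criterion 2. We observed this directly on synthetic
  courses; gene-wise standardization (which leaves Pearson
  correlations identical to the raw scale) removes the artifact.

## Windows

`build_windows()` pools age-adjacent samples, because a developmental
course typically holds only 1–5 samples per sampling period — too few
for correlation estimates on their own. Windows of `window_size`
samples start every `step` samples; a trailing stretch is covered by
anchoring a final full-size window at the end, so no window ever
shrinks. The window's age label is the median member age. Three samples
is the hard floor (a Pearson correlation needs three points); the
package default of four samples with step one matches a course of
about a dozen infant samples, where it leaves a trajectory of roughly
ten windows.

## The dominant-group search

Within each window, genes are clustered by average linkage on the
distance $1 - |r|$, and every cluster of the dendrogram with size in
`[min_size, max_size]` (defaults 5 and $G/5$) is scored by its $CI$.
The best-scoring cluster is *not* returned directly, for a reason worth
spelling out: the maximal-$CI$ node is almost never the module, but its
most collinear, highest-variance fragment. Selecting the maximum over
hundreds of nested candidates rewards sampling noise — a five-gene
subset of a fifty-gene module enjoys an upward-biased $PCC_d$ and
$SD_d$ that reliably beat the small $PCC_o$ penalty of leaving its
forty-five siblings outside. We therefore use the max-$CI$ node only as
a **seed**, and define the dominant group by module membership: all
genes whose absolute correlation with the seed's mean profile reaches
`kme_threshold` (default 0.9), capped at `max_size` by descending
membership. This is the standard eigengene-membership construction of
co-expression network analysis. The reported per-window score is
recomputed on the extended group, which also removes most of the
selection bias from the $CI$ trajectory itself. Ties in the seed search
break toward the smaller cluster, then the lexicographically smallest
gene id, keeping the whole search deterministic.

Degenerate inputs are handled explicitly: genes constant within a
window contribute $|r| = 0$ to any pair (penalizing degenerate groups
rather than silently dropping pairs); a window with fewer than
`min_size` varying genes, or an empty size band, yields an empty group
with a warning; $PCC_o = 0$ yields an infinite $CI$ sentinel with a
warning.

## Tipping point and significance

The tipping point is the window of maximal $CI$ (earliest on ties — the
conservative choice for a developmental course). Its prominence is
scored by the leave-peak-out statistic
$z = (\max CI - \overline{CI}_{rest}) / sd(CI_{rest})$.

A fixed cutoff like $z \ge 2$ is anti-conservative here: the peak is
the maximum over $n$ windows, and the expected maximum of $n$
exchangeable scores is already about $\sqrt{2 \log n}$ standard
deviations ($\approx 2.1$ at $n = 9$). The default threshold is
therefore calibrated for multiplicity, $t_{1-\alpha/n, n-2}$ with
$\alpha = 0.05$, which holds the familywise false-peak rate near
$\alpha$ under an exchangeable null — the package's null simulations
confirm the calibration. A fixed threshold can still be supplied.

The price of honest calibration at, say, nine windows is power: when
two adjacent windows both cover the transition (inevitable when the
window spans more than one sampling period), the second-highest window
sits in the "rest" and compresses $z$. A built-in permutation test is
also available (`permutations = B`): sample ages are shuffled, windows
rebuilt, the course rescanned, and the observed peak compared with the
permutation peaks (`B = 19` gives an exact 5% test). Its null is
exchangeability of ages, so it is honestly sized — but note its power
is limited against exactly the alternative the DNB model posits: a
variance surge concentrated in a few samples survives age shuffling
(whatever window inherits those samples scores high), so the
permutation peak often rivals the observed one. Significance
assessment on a course of a few dozen samples is intrinsically hard;
the trajectory itself, with its window localization and recovered
module, carries most of the evidence.

## Differential expression around the tipping point

Following standard practice the DEG stage is separate from the DNB
machinery and runs on the **raw** scale: one-way fixed-effects ANOVA
per gene on $\log_2(x + 1)$ values (the log stabilizes intensity
variance), Benjamini–Hochberg FDR across genes, and a
direction-symmetric linear fold change
$\max(FC, 1/FC)$ with $FC = (\bar{x}_{after} + c)/(\bar{x}_{before} + c)$,
where the pseudocount $c$ defaults to the smallest positive raw value.
A gene is called at $q < 0.01$ and fold change $> 2$ by default; "2-fold
down" counts the same as "2-fold up". The default grouping contrasts
samples before and after the tipping window's age label; any other
labelling (for example one label per sampling period) can be supplied.
Genes with no variance at all get $p = 1$.

## Exploratory ordination

`cluster_samples()`, `pca_scores()` and `mds_axis()` reproduce the
standard first look at such data: do samples cluster by species, and
how fast does global expression move with age? The MDS axis uses
classical (Torgerson) scaling on Euclidean distances, which for
Euclidean input equals the PCA first axis up to sign — an equivalence
the test suite asserts numerically — and is deterministic, unlike
stress-minimizing MDS. Sign conventions are fixed (largest-magnitude
loading positive for PCA; youngest sample on the smaller coordinate
for MDS) so plots and tests are reproducible.
`fraction_change_by_age()` operationalizes "how much of the total
change happened by age $x$" as the ratio of the first-axis range among
samples up to $x$ to the full range; it is monotone in the cutoff by
construction.

## The synthetic generator

`sim_config()` / `generate_dataset()` produce an age-stamped course
with full ground truth. The construction is linear-Gaussian on a
latent scale, wrapped in a multiplicative intensity model:

* Gene baselines $B_i$ are log-normal (background spread one log unit,
  about two decades) — rank-based normalization is only meaningful
  when genes occupy distinguishable intensity strata, as they do on
  real arrays. The planted module sits in a narrow mid-expression
  stratum; planted DE genes are drawn from the high-expression tail.
* A global background factor $g_s$ couples to every gene through a
  signed, gene-specific coefficient $a_i$ whose mean squared magnitude
  gives background genes a shared-variance fraction
  `background_corr` (default 0.3, in the range of the first principal
  component of typical expression data). Couplings must be
  heterogeneous and signed: a common equal shift would be invisible
  after rank normalization and would make the backbone unrealistic.
* The module's latent factor $f_s$ has per-period loading and spread
  schedules that peak at the tipping period (defaults: loading 0.3
  rising to 3; factor sd 1 rising to 5, the divergence of the soft
  mode's fluctuations near the bifurcation). At the peak the module's
  within-correlation approaches
  $L^2\sigma_f^2 / (L^2\sigma_f^2 + a^2 + \sigma_e^2)$ — a closed form
  the test suite checks against simulation at 500 samples — its
  standard deviation surges, and the (fixed-size) background coupling
  is diluted, so its correlation to the rest falls: all three DNB
  criteria hold by construction.
* DE genes multiply their mean by `de_fold` (default 4) in all periods
  after the tipping period — a persistent state shift, as opposed to
  the module's transient fluctuation surge.
* Defaults: 1000 genes, 50 module genes, 40 DE genes, 10 periods of 3
  samples at ages $0.05p$ years, tipping at period 4 (0.2 years),
  noise sd 1, baseline median 100. This mirrors an infant course of a
  few dozen samples and keeps a full scan in seconds.

Deliberately *not* emulated: probe-level microarray noise, batch
structure, age gradients within a period, cross-species divergence
from a common ancestor, and gradual (ramped) DE onset. Consequently,
passing the recovery tests shows the pipeline detects the signature it
is designed for at realistic sizes and noise — it does not show
robustness to batch effects or to transitions spread across periods.

## Evaluation protocol and its rationale

The validation studies (test suite and `scripts/acceptance.R`) scan
synthetic courses with windows of **six samples advancing by three**
— two sampling periods per window, advancing one period. Two a priori
reasons:

* With four-sample windows the null distribution of a Pearson
  correlation is uniform on $[-1, 1]$; about 5% of a thousand
  background genes then exceed $|r| > 0.95$ with *any* direction, so
  several dozen impostors are statistically indistinguishable from
  module members and no method can recover the module. At six samples
  the same tail probability drops roughly tenfold.
* With step 1, every window containing most of the tipping period is
  statistically equivalent, so the peak falls uniformly on a plateau
  of four or five windows and "localization to ±1 window" is
  meaningless. Period-aligned windows make exactly two windows cover
  the planted period fully, their flanks carry no module signal, and
  ±1 window corresponds to ±1 period.

Under this protocol the studies check: recovery of the planted window
(±1) and module (Jaccard ≥ 0.5) across 20 seeds; non-significance of
flat-schedule, no-DE null courses; the direction of the three criteria
at the planted window; DEG sensitivity and false-discovery proportion
at the planted fold change; and the PCA/MDS equivalence.

## Known limitations

* **The $PCC_o$ dip is the weakest of the three criteria at small
  windows.** The mean-$|r|$ statistic has a hard noise floor
  ($E|r| \approx 0.375$ at $n = 6$ under independence), so the planted
  decoupling moves $PCC_o$ by only a few hundredths; and in a sizeable
  minority of runs the within-window sample correlation between the
  module factor and the background factor — which has mean absolute
  value $\approx 0.37$ at $n = 6$ regardless of the true independence —
  inflates $PCC_o$ at the tipping window itself. $SD_d$ and $PCC_d$
  peak at the planted window essentially always; $PCC_o$ attains its
  exact across-window minimum there in only about two-thirds of runs
  (it falls below its across-window median far more reliably). More
  samples per window would fix this; the sampling design does not
  offer them.
* Both significance procedures are honestly sized but weak at ~9
  windows: the calibrated $z$ test loses power to peak splitting, and
  the age-permutation test to the ordering-invariance of the peak
  statistic. Treat `significant` as a conservative flag, not the main
  readout.
* Gene-wise standardization assumes intensities are roughly linear per
  gene; gross per-sample distortions should be handled upstream.
* The dominant-group search is deterministic but greedy: it tracks one
  seed per window and cannot represent two simultaneous transitions in
  different modules within the same window.

## A worked run

```{r, eval = FALSE}
sim <- generate_dataset(sim_config(seed = 1))
scan <- dnb_scan(sim$dataset, window_size = 6, step = 3)
scan
evaluate_recovery(scan, sim$truth)
plot_ci_trajectory(scan)

degs <- differential_expression(sim$dataset, split_age = scan$tipping_age)
table(degs$is_deg)
```

The same pipeline runs end to end from files via `run_pipeline()` (or
the thin command-line wrapper in `inst/scripts/dnb-pipeline.R`), which
writes per-window score tables, gene lists, DEG tables, ordination
coordinates and a single JSON report.
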