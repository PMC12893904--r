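# immunokit

Analytics for age-dependent immune signalling and treatment response.
immunokit is aimed at labs quantifying how immune organisation and
function erode with age — and whether an intervention restores them —
from spatial cell maps, cell×gene count matrices, TCR clonotype tables,
antibody-derived tag (ADT) counts and small assay read-outs. It
implements, as tested reusable functions:

- **Spatial interaction Z statistic** — for a cell-type pair, the
  standardised excess of close pairs over a local null,
  `z = (C(50µm) − µ̂)/√µ̂` with `µ̂ = C(150µm)·(50/150)²`, plus a
  label-permutation null as cross-check, and Pearson age-trend testing
  of z across timepoints.
- **Ligand–receptor scoring** — mean-expression communication scores
  `½(L̄_sender + R̄_receiver)` with age-stratified label-permutation
  p-values, Spearman age trends, Bonferroni correction and
  increasing/decreasing/flat calls.
- **Tissue-region identification** — graph heat-kernel smoothing
  `exp(−t·L_rw)` (t = 10) over the spatial Delaunay triangulation,
  then PCA + k-means.
- **Hierarchical cell typing** — read/gene QC filtering, median-depth
  normalisation, and three-level marker-panel k-means typing
  (19-gene level-1 panel into 24 clusters mapped to T / B /
  macrophage / dendritic cell, with lineage and T-state refinements).
- **Repertoire metrics** — CDR3-based clone calling, clonal
  proportions, Shannon diversity `H = −Σ p ln p` with equal-depth
  bootstrap downsampling, CLR normalisation of tag counts and tetramer
  gating at CLR > 1.7.
- **Immunological vaccination response age** — a quadratic
  age–response standard curve with 95% confidence bands, inverted per
  animal to an estimated age, with pooled two-sample t comparisons of
  treatment groups.
- **Assay summaries** — TREC −ΔCt from technical duplicates, trapezoid
  AUC over a time course, fold change from baseline.

A synthetic-data generator (`simulate_*`) reproduces the statistical
structure of every input — clustered point patterns with a tunable
cross-type attraction that can decay with age, negative-binomial count
matrices with region/type programs, bimodal tetramer signals, skewed
clone-size distributions, quadratic age–response cohorts, and
pharmacokinetic/qPCR series — so the full pipeline is testable without
animal data.

## Worked example

Simulate six tissue arrays whose cross-type attraction declines with
age, score the interaction, and test the trend:

```r
library(immunokit)
library(dplyr)

ages  <- c(4, 12, 20, 28, 36, 44)
sched <- data.frame(age = ages, alpha = seq(0.8, 0, length.out = 6))
maps  <- simulate_tissue_series(ages, sched, seed = 42)
zs    <- bind_rows(lapply(maps, interaction_zscore, "A", "B"))
zs[, c("age", "observed", "expected", "z")]
#>   age observed expected        z
#> 1   4      230    52.33 24.55934
#> 2  12      204    48.78 22.22506
#> 3  20      139    41.56 15.11620
#> 4  28       98    36.00 10.33333
#> 5  36       70    31.78  6.78038
#> 6  44       29    28.56  0.08317
zscore_age_trend(zs)
#>   type_a type_b       r         p n
#> 1      A      B -0.9935 6.259e-05 6
```

The 50 µm pair count collapses towards its 150 µm-based null
expectation as the attraction fades, and the Pearson trend of z against
age is strongly negative (r = −0.99, p = 6.3e−05) — the signature of an
interaction that is lost with age.

Fit the age–response standard curve and read off immunological ages for
two treated groups (responses in % tetramer+ CD8 T cells):

```r
curve <- fit_quadratic(simulate_cohort(seed = 42))
curve
#> <age_response_curve> response = 7.29 -0.1872*age +0.001299*age^2
#>   n = 32, df = 29, R^2 = 0.9470, ages 6-72 weeks

dfi <- invert_age(curve, c(2.03, 2.36, 1.95, 2.92))$est_age  # treated
luc <- invert_age(curve, c(1.32, 0.86, 1.38, 1.48))$est_age  # control
compare_groups(dfi, luc)
#>   estimate1 estimate2      t df       p degenerate
#> 1     35.33     49.05 -4.037  6 0.00683          FALSE
```

Although all animals are chronologically 52 weeks old, the treated
group's vaccine responses correspond to ~35-week-old animals versus
~49 weeks for controls (pooled t-test, p = 0.007): the treatment
rejuvenates the measured response by roughly 14 weeks in this simulated
cohort.

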