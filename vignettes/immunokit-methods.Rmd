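---
title: "Methods: spatial, repertoire and calibration analytics in immunokit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatial, repertoire and calibration analytics in immunokit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(immunokit)
library(dplyr)
```

immunokit quantifies how immune cell organisation and function change with
age and with treatments intended to rejuvenate immunity. It covers six
analysis stages — a spatial interaction statistic with age-trend testing,
permutation-scored ligand–receptor communication, heat-kernel tissue-region
identification, hierarchical marker-based cell typing, TCR/tetramer
repertoire metrics, and an inverse-calibrated "immunological vaccination
response age" — plus a synthetic-data generator that emulates the
statistical structure of each input so the whole pipeline is testable
without animal data. This vignette explains the models, their assumptions,
the tunable parameters, and the design decisions taken where the underlying
procedures left choices open.

## The spatial interaction Z statistic

For a pair of cell types on one tissue array, let $C(r)$ be the number of
cross-type cell pairs within Euclidean distance $r$ (µm). The statistic
compares the close-range count against a null built from a wider local
neighbourhood:

$$ z \;=\; \frac{C(r_\mathrm{obs}) - \hat\mu}{\sqrt{\hat\mu}},
\qquad \hat\mu = C(r_\mathrm{null})\left(\frac{r_\mathrm{obs}}
{r_\mathrm{null}}\right)^2 $$

with defaults $r_\mathrm{obs} = 50$ µm and $r_\mathrm{null} = 150$ µm, so
the area ratio is $1/9$. Under local homogeneity at the 150 µm scale, the
close pairs are a thinned subset of the wide-radius pairs and
$\hat\mu$ estimates their expectation; the Poisson standard deviation
$\sqrt{\hat\mu}$ reflects that close-pair counts are sums of sparse
indicators. "Interaction frequency" is read as a raw pair count: that is
the only reading that uses both radii and needs no further inputs. A
label-permutation null (`null_mode = "permutation"`) is provided as a
cross-check; there the null mean and sd come from re-labelling cells on
the array, and the wide-radius count is only a diagnostic.

Age trends are tested by Pearson correlation of $z$ against age across
arrays, with the usual $t$ transform on $n-2$ degrees of freedom.
Replicate arrays at one age are averaged (with a message) first.

**Known limitations.** Distances are 2-D Euclidean with no edge
correction: both radii lose disc area near the boundary, and the loss
partially — not exactly — cancels in the ratio. The residual bias is
positive and shrinks roughly with the squared ratio of radius to domain
size. For this reason the tissue simulator defaults to a 5,000 µm square
with 300 cells per type: at that geometry the null mean of $z$ on
complete-spatial-randomness (CSR) tissues is ≈ 0.1 with sd ≈ 1.0, while
on a 1,500 µm domain the bias would reach ≈ 0.9. Arrays much smaller than
~20× the null radius need an edge-corrected statistic that this package
deliberately does not implement (no Ripley-K machinery, no inhomogeneity
correction).

## The synthetic tissue generator

`simulate_tissue()` uses Neyman–Scott-style parenting: parent-type cells
are uniform on the domain; each offspring cell is, with probability
$\alpha \in [0,1]$, displaced from a uniformly chosen parent by an
isotropic Gaussian (`cluster_sd`, default 25 µm), else placed uniformly.
$\alpha$ is a single monotone dial on the interaction statistic:
$\alpha = 0$ is CSR (the calibration null), and $z$ increases strictly
with $\alpha$. Out-of-domain Gaussian draws are resampled rather than
clipped to avoid boundary pile-up. `simulate_tissue_series()` derives
per-age seeds from `(seed, age)` so adding an age never perturbs the
other ages' maps. Cell density (~600 cells on 25 mm²) is a convenience
choice tied to the null-calibration geometry above, not an estimate of
real tissue density; real thymic arrays are far denser, which only makes
the Poisson approximation more comfortable.

## Ligand–receptor scoring

The communication score for (ligand $L$, sender $S$) → (receptor $R$,
receiver $T$) is the arithmetic mean of the two subpopulation means on
log-normalised expression,
$\tfrac12(\overline{L}_{S} + \overline{R}_{T})$ — the mean-expression
convention of the common cell–cell communication frameworks. The
permutation test shuffles cell-type labels *within an age group* (never
across ages, so the null preserves age composition) and uses the add-one
estimator $p = (1 + \#\{\text{perm} \ge \text{obs}\})/(n_\mathrm{perm}+1)$,
which is never zero and has resolution $1/(n_\mathrm{perm}+1)$. Age
trends use Spearman rank correlation (midranks for ties; exact
enumeration p-values for up to 9 ages, $t$ approximation beyond),
Bonferroni-corrected over the $m$ tested interactions; an interaction is
"increasing"/"decreasing" only when its corrected p-value falls below
0.05 (configurable), otherwise "flat". Both the per-age permutation
p-values and the score trajectories are emitted, since either can feed
the trend step.

## Tissue-region identification by heat-kernel smoothing

Regions are large-length-scale expression patterns. The pipeline is:

1. `delaunay_adjacency()` — the spatial neighbour mesh is the Delaunay
   triangulation of cell positions (duplicate or collinear points are
   errors; a `prune_above` cutoff can drop sliver edges).
2. `heat_smooth()` — each gene column is filtered by the graph heat
   kernel $e^{-tL_\mathrm{rw}}$, $L_\mathrm{rw} = I - D^{-1}A$, default
   $t = 10$. Random-walk normalisation is chosen because it preserves
   constant signals exactly and makes $t$ degree-independent; the
   procedure that motivated this module does not pin down the
   normalisation, and this choice is recorded in output metadata. The
   kernel is evaluated per connected component via the symmetric
   Laplacian's eigendecomposition, which is exact; the test suite holds
   it to ≤ 1e-6 relative error against an independent dense
   matrix-exponential oracle (in practice agreement is ~1e-13). Dense
   eigendecomposition costs $O(n^3)$ per component — fine into the few
   thousands of cells, the intended scale.
3. `region_call()` — PCA (per-gene centring, no rescaling, since the
   matrix is already preprocessed upstream) and k-means on the top PCs
   (10 restarts, fixed seed; k-means rather than neighbour-graph
   clustering to avoid smoothing-induced spatial autocorrelation
   artefacts). `k` is user-chosen; there is no automatic model
   selection. Labels are relabelled by decreasing region size and
   returned 0-based.

The `"regions"` simulator mode plants contiguous vertical bands with
marker programs (default mean multiplier 3, negative-binomial noise with
size 2 — the moderate fold changes and overdispersion typical of in-situ
panels). At that SNR the pipeline recovers the bands with adjusted Rand
index ≳ 0.9; at a low SNR (multiplier 1.5) raw-matrix clustering
collapses (ARI ≈ 0.1–0.2) while the smoothed pipeline still reaches
≈ 0.9 — the motivating property of the low-pass filter. What the
synthetic tissue does *not* emulate: irregular region geometry, gradual
boundaries, segmentation noise, or gene–gene correlation beyond the
region programs; passing recovery tests here does not guarantee the same
ARI on real tissue.

## Quality control, normalisation and hierarchical typing

`qc_filter()` excludes cells with fewer than 2 total reads *or* fewer
than 2 detected genes. The two conditions could in principle be required
jointly; the OR reading is implemented because it is the superset of the
joint reading and standard QC practice — the boundary behaviour
(1 read excluded; 2 reads over 2 genes retained; 5 reads in 1 gene
excluded) is pinned by tests. `preprocess_expression()` rescales each
cell to the cohort-median total, applies `log1p`, and centres/scales
each gene to unit variance.

`hierarchical_classify()` implements three-level typing: cells with zero
raw expression across the level-1 panel are removed with a logged
reason; k-means (default $k = 24$) on the 19-gene level-1 panel; each
cluster is mapped to the type whose signature — the mean of that type's
designated markers in the cluster centroid — is maximal, or
`"unassigned"` when no signature is positive (this mapping replaces the
manual cluster annotation a human would do; signatures are
user-supplied). The procedure recurses per type with level-specific
panels and $k$, with level 3 (a 15-marker T-state panel) applied under
CD4/CD8 T cells. Default panels use generic mouse marker names and are
intended for the synthetic fixture; the `"types"` simulator mode
elevates each type's signature markers 8-fold (lineage markers are
essentially on/off), at which the level-1 accuracy is ≈ 0.99, degrading
monotonically as the effect size shrinks.

## Repertoire metrics

Clones are called on CDR3 amino-acid junctions: the clone key
concatenates per-chain junctions (TRA|TRB when both present, single
chain otherwise — the fallback keeps orphan chains usable). Shannon
diversity $H = -\sum p_i \ln p_i$ is reported in nats; with
`downsample_n` set, $H$ is averaged over `n_boot` (default 100)
bootstrap downsamples without replacement, the equal-depth convention
for comparing conditions. ADT tag counts are CLR-normalised per tag
across cells with a `log1p` pseudocount (the margin is not dictated by
the upstream convention and is recorded in the output); the tetramer
gate calls a cell antigen-specific when its CLR signal strictly exceeds
1.7. The ADT simulator draws a log-normal mixture whose default modes
(background $e^{1.6}$, positive $e^{5}$, log-sd 0.5) put the gate
threshold ≈ 4 background sds above the background CLR mode, so gate
sensitivity and specificity both exceed 0.95 by design margin, not by
tuning.

## The immunological vaccination response age

`fit_quadratic()` fits `response = a + b·age + c·age²` by ordinary least
squares and reports the coefficient covariance, $R^2$ and residual
degrees of freedom $n - 3$ (32 calibration animals — 8 ages × 4 — give
df = 29). `predict_band()` gives pointwise confidence bands for the
*fitted mean*, $\hat y_0 \pm t_{df}\sqrt{x_0^\top V x_0}$; prediction
bands for new animals would be wider, and the choice is switchable in
principle but the confidence-band reading is the default because the
curve is used as a standard curve. `invert_age()` solves the quadratic
per animal, keeps real roots inside the calibration age range (default
extrapolation margin 0 — no silent extrapolation), and when both roots
are admissible picks the one on the monotone branch covering the
majority of calibration ages; `root_status` records `unique`, `selected`
or `out_of_range`. Inverting *individual* animals and then comparing
groups with a pooled two-sample t-test matches a 4-vs-4 treated/control
design; inverting group means would discard the between-animal variance
the t-test needs.

The cohort simulator's default quadratic (6.8, −0.16, 0.001; response in
% tetramer+ of CD8) declines from ≈ 5.9% at 6 weeks to ≈ 0.5% at 72
weeks, monotone over the calibration range (vertex at 80 weeks), with
Gaussian noise sd 0.4 giving $R^2 \approx 0.95$ — a clean standard-curve
regime. In simulation, 95% bands cover the true mean at a design age in
≈ 95% of replicates, and the mean estimated age of true-52-week
responders is within ±3 weeks of 52.

## Assay summaries

`trec_neg_delta_ct()` averages technical duplicates and returns
$-(\overline{Ct}_\mathrm{TREC} - \overline{Ct}_\mathrm{TCRA})$, so higher
values mean more recent thymic emigrants. `auc_trapezoid()` integrates a
concentration time course by the trapezoid rule from 0 to `t_end`
(default 48 h), linearly interpolating when `t_end` falls between
observations; raw (not baseline-subtracted) values are integrated, and
callers can subtract beforehand if desired. `fold_change_series()`
divides by the t = 0 baseline; any organ-weight normalisation is a
caller-supplied divisor applied before it.

## Determinism, numerical choices and problem sizes

Every stochastic function takes an explicit integer `seed` and restores
the caller's RNG state; identical inputs give byte-identical outputs.
Derived seeds (per age, per hierarchy level) are mixed arithmetically so
that adding a condition never perturbs the streams of the others.
k-means uses 10 restarts under the fixed seed; region/cluster labels are
deterministic given inputs. Degenerate inputs (constant series, zero
null counts, zero pooled variance, rank-deficient designs) raise typed
errors rather than returning NaN, except the zero-variance t-test case,
which reports the limiting p with a `degenerate` flag.

The statistical checks in the test suite run at the sizes a desk-scale
replication supports — 500 CSR tissues of ~600 cells for null
calibration, 200 replicates of 6-age series for trend power, 2,000
replicates for band coverage and permutation calibration, 1,200-cell
tissues for region recovery — all chosen so the whole suite completes in
a few minutes on one CPU while keeping Monte-Carlo error well inside the
asserted bands.
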