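---
title: "Cross-platform normalization: models, statistics, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-platform normalization: models, statistics, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crossnorm)
```

## The problem

Gene-expression values measured on different microarray platforms are not
directly comparable: probe sequences, labeling chemistry, and detection
method all distort the measured signal in a gene-dependent way. Meta-analysis
sidesteps the problem by combining per-platform *results*; cross-platform
normalization instead transforms the expression values themselves so that
samples from two platforms can enter one analysis. `crossnorm` implements
nine published normalization methods behind a single interface, an
evaluation harness that quantifies how well each method removes platform
effects while preserving treatment effects, and a simple physical/statistical
model of what a platform effect is.

All methods operate on a `combined_dataset`: two gene-aligned matrices of
natural-log expression (one per platform) plus a sample annotation giving
each sample's platform and treatment. Inputs are assumed log-transformed;
the model-based methods rely on approximate normality and are known to
behave poorly on raw-scale data.

## A model of platform effects

At hybridization equilibrium the measured signal for one probe follows a
Langmuir saturation curve,

$$ S = \frac{I\, g_0\, p_0\, (k_+/k_-)}{1 + (k_+/k_-)\, g_0}, $$

where only the target concentration $g_0$ reflects expression; the label
intensity $I$, probe-site quantity $p_0$, and equilibrium ratio $k_+/k_-$
are platform properties (`hybridization_signal()`). On the log scale, and
away from saturation, platform properties enter mainly as a per-gene
*location shift*, which motivates the additive model

$$ y_{ijk} = T_i + P_j + C_{ij} + \varepsilon_{ijk} $$

for treatment $i$, platform $j$, repetition $k$: treatment effects $T$,
platform effects $P$, treatment–platform interactions $C$, and replicate
noise. `anova_interaction()` tests $C$ gene-by-gene (the F-test of the full
against the additive two-way model; all genes share one design, so residual
sums of squares come from a single QR factorization per model), and
`estimate_pi1()` converts the p-value distribution into an estimate of the
fraction of genes with real interactions.

Two identifiability conventions matter. A constant interaction is
indistinguishable from a platform effect, so the interaction test targets
interaction *variation*. And in `platform_effect_truth()` the interaction
matrix is row-centered across platforms ($\sum_j C_{ij} = 0$, row means
absorbed into $T_i$); under that convention the transfer residual
`residual_difference()` — the error left when a location shift learned on
one study is applied to another in the missing-group layout, with platform
effects assumed uniform across studies — is exactly
$T_1 - T_2 + \tfrac12 \sum_{ij} (-1)^{j-1}(C_{ij} - C^\diamond_{ij})$.
Column-centering $C$ as well would silently move the interaction information
into $P$ and void the formula; we verified the chosen convention against a
simulate-then-shift oracle on random effect sets (agreement to 1e-10). The
least-squares optimal shift itself is
$\eta_j = P_j + \sum_i n_{ij} C_{ij} / \sum_i n_{ij}$
(`optimal_location_shift()`): with one treatment group, or without
interactions, a location shift removes platform effects exactly; with
interactions a residual necessarily remains.

## The nine methods

**Marginal (rank/distribution) methods.** `quantile_normalize()` maps every
sample onto the per-rank mean of all pooled samples (via
`limma::normalizeQuantiles`, ties averaged). `mrs()` maps each query-platform
sample onto the per-rank *median* of the reference platform's samples,
leaving the reference untouched. `gq()` runs MRS and then aligns per-gene
medians exactly; note that this second step shifts each gene by its own
constant, so unlike MRS it does not preserve rank order *within* query
samples — that is the price of exact per-gene median agreement. `qd()`
replaces values by centered equiprobable bin codes (default 8 bins, a
configurable choice since the original bin count is not documented);
`nordi()` codes each value −1/0/+1 against normal tails fitted after
iterative two-sided Grubbs outlier removal (defaults p = 0.01, alpha = 0.05;
the trimming stops when the Grubbs test no longer rejects). `distran()`
clusters samples by k-means (k = number of treatment groups, the usual
choice when group labels are withheld) and equalizes per-rank means within
each cluster, with the per-cluster target the unweighted mean of the two
platforms' rank-mean vectors so a larger platform cannot dominate.

**Model-based methods.** `eb_adjust()` is an empirical-Bayes batch
adjustment with parametric priors: genes are standardized by the grand mean
and pooled within-platform scale; platform means get a normal prior and
platform variances an inverse-gamma prior, both fitted by method of moments
across genes; the coupled posterior updates are iterated to a 1e-4 fixed
point (at most 500 iterations) and values are rebuilt on the original
scale. No covariates are used: we target applications where treatment labels
are unavailable. `xpn_normalize()` fits the block model
$x_{gj} = A_{\alpha(g)\beta(j)} b_{gp} + c_{gp} + \sigma_{gp}\varepsilon$
over gene clusters $\alpha$ (default K = 3) and assay clusters $\beta$
(default L = number of treatment labels), alternating closed-form updates of
the block means and the per-gene sensitivities/offsets/noise until the
log-likelihood stabilizes (relative change below 1e-6, at most 200 inner
iterations), then replaces $b, c, \sigma$ by their cross-platform averages
($\sigma$ on the variance scale) and rebuilds each value from its
standardized residual. The whole procedure is repeated over 30 random
clusterings and averaged.

**Sample clustering.** Joint k-means on raw samples would simply split the
data by platform whenever gene-level platform shifts are present — the
spanning requirement (every assay cluster must contain both platforms) could
then never be met. Both DisTran's and XPN's clustering therefore run on
genes standardized within platform (mean 0, sd 1 per gene per platform),
which blinds the clustering to location-type platform effects; XPN's
`modified = TRUE` variant instead clusters each platform separately and
matches clusters by greedy maximum centroid correlation
(`match_clusters()`).

**Distance weighted discrimination.** `solve_dwd()` labels samples by
platform and solves

$$ \min_{w,\beta,\xi} \; \sum_i \frac{1}{r_i} + c \sum_i \xi_i
   \quad \text{s.t.} \quad r_i = y_i(w \cdot x_i + \beta) + \xi_i,\;
   r_i > 0,\; \xi_i \ge 0,\; \lVert w \rVert_2 \le 1. $$

Profiling out the slack turns this second-order-cone program into an
equivalent smooth convex problem with the $C^1$ DWD loss
($V(u) = 1/u$ above $1/\sqrt{c}$, linear below), minimized by accelerated
projected gradient on the unit ball to a KKT residual below 1e-6. The
penalty defaults to $100 / \mathrm{median}(d)^2$ over between-class
distances, the customary heuristic. Tests verify the attained objective
against an independent general-purpose optimizer. `dwd_normalize()`
mean-centers genes, fits the direction, and subtracts from each platform its
mean projection along the *unit* direction (the optimum can be interior when
platforms overlap, so the raw $w$ must be normalized before projecting);
within-platform differences are untouched by construction. The resulting
per-platform location vectors (`dwd_shift`) can be saved, transferred to
another dataset (`transfer_shift()`, the only route available when a
treatment group is missing from one platform), or permuted as a negative
control (`scramble_shift()`, one shared gene permutation so the norm and
difference structure survive while gene correspondence is destroyed).

## Evaluation statistics

`mean_mean_r2()` measures inter-platform concordance as the squared Pearson
correlation between per-gene treatment-group means on the two platforms; for
technical replicates of one RNA pool the ideal is the line $y = x$. (The
concordance correlation coefficient, which also penalizes departures from
$y = x$, is available via `ccc = TRUE`; $r^2$ remains the headline statistic
for comparability.) Differential expression uses per-gene two-sided Welch
t-tests (`welch_pvalues()`, vectorized and verified against `stats::t.test`)
converted to q-values by the Storey–Tibshirani estimator (`qvalues()`):
$\hat\pi_0(\lambda)$ on a 0–0.95 grid, cubic smoothing spline with 3
effective degrees of freedom, evaluated at the largest $\lambda$ and clamped
to (0, 1], followed by the step-down q-value recursion. With fewer than 20
p-values the spline is unreliable and $\hat\pi_0$ is pinned at 1 with a
warning.

The empirical cdf of a q-value list on an FDR grid of step 0.001
(`roc_like_curve()`) gives the fraction of genes called significant as a
function of the FDR threshold. Gene-set union and intersection of two lists
correspond to gene-wise minimum and maximum (`combine_qlists()`). The two
headline areas (`detection_areas()`, trapezoid rule on [0, 1]) are
*over-detection* `o` — genes detected with merged data but by neither
platform alone — and *under-detection* `u` — genes detected by both
platforms independently but lost after normalization. Both are non-negative
by construction, and neither can be optimized alone: wiping out treatment
effects zeroes `o` at the cost of a large `u`. The grid includes t = 0
(height = fraction of exact-zero q-values); at t = 1 everything counts as
detected.

Method distributions are compared by medians with two-sided Mann–Whitney
tests at level $\alpha/n^2$ (`rank_methods()`; $\alpha$ defaults to 0.05,
with $n$ the number of methods including controls), and variance
differences by the Brown–Forsythe test on absolute deviations from group
medians (`brown_forsythe()`, delegated to `car::leveneTest`).

## The smoothed-bootstrap benchmark

`run_benchmark()` draws, per replicate, a smoothed bootstrap of each
platform: sampling with replacement strictly within treatment groups, plus
zero-centered Gaussian noise of sd 0.1 (`smoothed_resample()`; the smoothing
makes resampled values almost surely distinct, inflating per-gene variance
by almost exactly 0.01). Each method is applied to the resampled pair;
native single-platform curves come from independent resamples with the two
differential-expression groups doubled in size, keeping the total sample
count per curve fixed. Two controls bracket the methods: `resample.1/2`
treat two independent resamples of one platform as a platform pair (the
best any method could do), and `no.norm` is the merged data unadjusted.
Method failures are logged and recorded as `NA` for that replicate; a
method failing in over 20% of replicates is abandoned. `unequal_design()`
builds the crossed unequal-group layouts (e.g. 15/5 on one platform, 5/15 on
the other), and `transfer_experiment()` runs the missing-group experiment
with its four modes (self-transfer, transfer, no-transfer, scrambled);
concordance is undefined there because each treatment lives on only one
platform, so only `o` and `u` are reported. Native curves in the
missing-group experiment come from the full test data — a choice the
output's provenance does not hide, since the reduced data alone cannot
separate treatment from platform.

## The synthetic generators

Three generators supply ground-truth data. `simulate_linear()` draws the
additive model directly: per-gene baselines N(7, 1) on the log scale,
treatment effects of sd 1 for a 30% differentially expressed fraction,
per-gene platform shifts of sd 1, interactions (mirrored and row-centered,
scale 0.5) for a configurable fraction of genes, and replicate noise of
sd 0.1 — two treatment groups of 15 replicates per platform by default, a
desk-scale version of a typical two-platform benchmark.
`simulate_mechanistic()` instead pushes per-gene target concentrations
through the saturation model with per-platform parameter draws: platform 1
sits in the near-linear regime ($k g_0 \sim 0.01$) and platform 2 partially
saturates ($k g_0 \sim 1$), mimicking the chemiluminescence-vs-fluorescence
dynamic-range contrast, so platform effects are nonlinear, gene-dependent,
and interact with treatment by construction. `simulate_xpn_model()` emits
data exactly from the XPN generative model for recovery tests. All
generators are pure functions of their configuration and seed.

What the simulations do *not* emulate: probe-level effects, missing values,
scanner or image-processing artifacts, correlated gene modules, and
real-data departures from normality. Passing the benchmark here shows a
method removes location/saturation-type platform effects under the stated
model, not that it handles every real dataset.

On these simulations the benchmark reproduces the expected grouping: the
four location-shift methods (DWD, EB, GQ, XPN) sit near the resample
controls in concordance and under-detection, while QN, MRS, and DisTran —
which only match marginal distributions and cannot repair gene-specific
shifts — sit near the unnormalized control, whose over-detection is zero
(platform effects cancel between equally sized groups) but whose
under-detection is large.

## Numerical choices and problem sizes

Ties map to averaged reference values everywhere, making all rank mappings
deterministic and symmetric. Zero-variance genes under the Welch test yield
p = 1 (equal means) or p = 0 (unequal); zero-variance centroids correlate at
−∞ in cluster matching; XPN noise variances are floored at 1e-12. k-means
uses 10 restarts per attempt with seeded redraws (20 for DisTran's spanning
requirement, 100 for XPN's). All stochastic functions take an explicit seed
and restore the caller's RNG state.

The test suite and the acceptance script run at deliberately desk-scale
sizes chosen once: 1000–2000 genes, 5–20 replicates per group, 20 bootstrap
replicates — small enough for a laptop run of a few minutes, large enough
that every qualitative contrast (method grouping, control ordering,
estimator calibration) is stable across seeds. The `pi1` estimator's
sampling sd at 2000 genes is about 0.05, which the calibration tests
acknowledge.

## Known limitations

Only two platforms per run are supported (multi-platform integration would
be pairwise). The EB variant is parametric-prior only and ignores
covariates by design. DWD here is a normalization device, not a classifier:
no multiclass or kernel variants. Transfer of location shifts across studies
assumes platform effects are uniform between them — the transfer residual
formula quantifies exactly how treatment–platform interactions break that
assumption, and the scrambled control shows what failure looks like
(inflated over-detection).
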