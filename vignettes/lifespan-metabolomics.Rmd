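---
title: "Modelling plasma metabolome and lipidome change across the lifespan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling plasma metabolome and lipidome change across the lifespan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lifespanomics)
```

This vignette is the package's own account of its methods: the models,
their assumptions, the tunable parameters and their defaults, what the
synthetic cohort generator does and does not emulate, and the numerical
and design choices made where more than one reasonable option existed.
It states no empirical result that the test suite or the acceptance
script does not itself compute.

## The data model

A `FeatureTable` is a nonnegative abundance matrix (features × samples,
arbitrary intensity units) tagged with a modality (`metabolite` or
`lipid`) and a normalization state (`raw`, `total_sum`, `median_ratio`).
Sample metadata carries age in years, sex (F/M) and one of seven ordered
life-stage groups, newborn (cord blood, age exactly 0) through late
adulthood. The default group boundaries are 0 (point), (0,6), [6,12),
[12,19), [19,40), [40,65) and ≥ 65 years; they are configurable, and the
65/40-year cut-offs are reused by the elderly-vs-young contrast of the
biomarker stage.

**Normalization.** Total-sum normalization divides each sample column by
its sum (columns then sum to 1); median-ratio normalization divides by
the column median over *all* values including zeros, falling back to the
nonzero median when the all-value median is 0 — zero-inflated intensity
matrices make the plain median fragile, and the fallback keeps the
operation defined without imputing. Zeros pass through normalization
untouched; no pseudo-count is added. All log transforms downstream use
`log(x + offset)` with a configurable offset defaulting to half the
smallest positive value in the table, so normalization itself stays
linear and the offset is an explicit, inspectable choice.

**Filtering.** A feature is kept when its nonzero fraction strictly
exceeds 50% in at least one group (a feature nonzero in exactly half of
every group is dropped), and, where QC replicate columns exist, when its
QC coefficient of variation is strictly below 0.30. Both filters emit a
drop report (feature, reason). Batch correction is out of scope; a
no-op hook with the pass-through signature lets externally corrected
matrices be injected.

## The synthetic cohort generator

Every downstream stage is exercised on generated cohorts with known
ground truth. Abundance is

    x = base_level · exp( f(age) + δ_sex · I(male) + N(0, σ) )

with f one of five log-scale trajectory kinds: null (flat), linear
(β per year), peak (a Gaussian bump of given center, width and height —
the minimal shape able to produce crest-style nonlinear trajectories),
step (a shift at a given age) and group marker (a shift in one
life-stage group). Zeros are injected uniformly at a configurable rate.
Defaults emulate the study conditions: 136 subjects split nearly evenly
over the seven groups, ages uniform within each group's boundaries
(newborns exactly 0), noise σ = 0.3 on the natural-log scale, 5% zero
inflation, and a small sex shift (0.05) on trend-carrying features.
The lipid panel spans 27 classes with class-appropriate chain counts;
saturated SPH species carry a newborn group-marker shift (+1.5 log
units) and polyunsaturated TG species a linear rise (+0.02/y), giving
the saturation analytics and the cross-modality network a known truth.

Two properties are deliberate: one master seed derives a per-feature
seed sequence, so appending feature specs never perturbs the features
already generated; and scaling every feature's `base_level` is invisible
after total-sum normalization, which the tests assert.

What the generator does *not* emulate: instrument drift and batch
structure, realistic between-feature correlation blocks (features are
conditionally independent given age/sex/group), non-Gaussian noise
tails, and informative missingness (zeros are uniform, not
intensity-dependent). Passing tests therefore demonstrate that the
algorithms recover the structure they target under clean, known
conditions — not that any specific biological cohort will behave as
tamely.

## Differential expression and enrichment

Two-group comparisons use a two-sided t-test on log10 abundance with
Welch's unequal-variance form by default: variances across life stages
differ visibly in this kind of data, and the pooled-variance form is
available by argument for exact textbook reproduction. BH adjustment is
applied across all features within one comparison (not across
comparisons), and a feature with zero variance in both groups is flagged
degenerate, reported `ns`, and excluded from the BH family rather than
contributing an undefined p-value.

Newborn profiling runs A against each of the six later stages and
reports upset-style intersection counts of the significant sets. Group
markers use the pooled-rest design: a feature marks group *g* when it is
significantly up in *g* versus all remaining samples pooled *and* its
maximal group mean is attained in *g* — the pooled-rest test is more
stable than six pairwise tests and the maximal-mean condition enforces
specificity. The class-level change score is this package's own
definition, `(n_up − n_down) / n_class` at the comparison's q threshold,
bounded in [−1, 1]; the prior art it substitutes for is external and not
reproduced here, which the documentation flags.

Pathway over-representation takes local GMT files, restricts each set to
the tested universe (dropping outside members with a warning), requires
at least 2 in-universe members, computes the one-sided hypergeometric
upper tail, and BH-adjusts across tested sets.

## Linear and nonlinear age trajectories

The linear model `y = α + β₁Age + β₂Sex + ε` is fitted per feature on
log10 abundance by OLS over a shared design matrix, so a whole table is
one QR decomposition. The age term's p-value is a Type II partial
F-test — the residual-sum-of-squares comparison against the design with
age removed, which for this additive model equals the classical Type II
ANOVA — and the test suite cross-checks it against an independent Type
II ANOVA implementation. No age×sex interaction is fitted, matching the
sex-as-covariate design.

LOESS trajectories use locally weighted quadratic regression (tricube
weights) with span 0.75 by default, evaluated on a 50-point age grid
within the observed range, then z-scored over the grid. Wide spans
over-smooth: a crest of width ~8 years is displaced by several years at
span 0.75 and recovered within ±3 years at span 0.5, so analyses that
care about crest location should narrow the span; the trade-off is
documented rather than hidden behind automatic span selection, which is
a non-goal. Numerically flat fitted curves cannot be z-scored and are
excluded with a flag. Clustering is agglomerative (Euclidean distance,
complete linkage by default, ward/average by argument) with the tree cut
at k = 8, the convention for this analysis; the input rows are sorted by
name before clustering so assignments are invariant to feature order,
and fewer distinct curves than k is an error rather than silently empty
clusters.

## DE-SWAN

For each center c, samples in [c − w/2, c) form the young stratum and
(c, c + w/2] the old stratum; a sample exactly at the center belongs to
neither (the half-open convention is asserted on a crafted fixture). Per
feature, log10 abundance is regressed on the stratum indicator plus sex;
p-values come from the stratum term's partial F-test, BH within center;
centers with fewer than 3 samples on either side are skipped and
recorded. The headline configuration walks 1-year centers with a
20-year total window; the published description of this analysis names
both a 20-year window and a 5-year increment in different places, so
both are exposed (`window = 20` default, `window = 5` variant) rather
than silently reconciled. Peak calling is deterministic: a center is a
peak when its count is maximal within ±5 years and exceeds the curve
median by at least 2 raw (unscaled) median absolute deviations; runs of
tied neighboring candidates collapse to their middle center. The raw
MAD was chosen over the Gaussian-consistent scaling because the curve is
a count series, and with the consistency constant the threshold would
only loosen.

## PVCA and networks

PCA operates on the log2 matrix, features centered (scaling optional),
constant features dropped with a warning. PVCA retains the smallest set
of leading PCs covering ≥ 60% of variance (a standard convention; the
retention rule is an argument), fits each retained PC's scores with
random effects for age, sex and age×sex, and averages the per-PC
variance fractions with eigenvalue weights before normalizing to sum 1.
Age enters as the categorical seven-group factor: a classical
variance-component decomposition needs grouping levels, and the
life-stage design is the study's own stratification. Variance components
are REML estimates with non-negativity; if the mixed model fails, a
method-of-moments fallback (between-level variance of level means,
truncated at zero) is used and logged. A single-level factor gets
fraction 0 with a warning.

The metabolite–lipid network ranks each side's features by |β_age| among
those with q < 0.05 (age-increasing by default), keeps the top 50 per
side, scores all cross-pairs by Spearman correlation (average ranks for
ties, t-approximation p-values), and retains edges with |ρ| > 0.5 and
p < 0.05, annotated with both endpoints' slopes. Output is an edge TSV
plus GraphML for network viewers.

## The aging clock

The clock searches α ∈ {0.1, …, 0.9} × training fractions
{0.5, 0.6, 0.7, 0.8}. Splits are stratified by life-stage group so no
age range is absent from either side; λ is chosen by 10-fold CV on the
training set; the combination with the smallest held-out MAE wins, and
its training-set coefficients at the chosen λ are the clock. The CV λ
rule defaults to the one-standard-error choice rather than the CV
minimum: the reference clocks in this literature are sparse relative to
their feature pools, and the 1-SE rule is the standard parsimony
convention; `lambda.min` is an argument. Predictors are standardized
inside the penalized fit, so feature-wise affine rescaling does not
change predictions (asserted). Fold assignments are drawn from seeds
derived from the master seed, making the whole procedure reproducible
bit-for-bit.

Reduction ranks the clock's nonzero features by |coefficient| × sd — the
standardized magnitude, reading "contribution to the model" as the
fitted coefficient after standardization; ranking by univariate age
correlation is available by argument. Elastic-net refits on the top
2…J features (80% training split fixed across J) give an accuracy curve
(Pearson r of predicted vs chronological age by default, MAE by
argument), and a two-segment broken-stick regression — exhaustive
least-squares over a 0.1-step knot grid — estimates the breakpoint,
rounded to the nearest feature count. A near-zero slope change flags the
breakpoint low-confidence instead of failing.

The biomarker panel intersects (1) features significantly up in the
elderly (≥ 65) versus young (< 40) — the comparator mirrors the ROC
task's classes, since the contrast the published selection used is not
stated — with (2) significant positive linear age slopes and (3) nonzero
clock coefficients. The panel classifier is penalized logistic
regression on those features, evaluated by stratified 10-fold CV ROC
with middle-aged samples (40–64) excluded; the fold count shrinks with a
warning when a class is smaller than the fold count. AUC is computed by
trapezoid integration of the empirical ROC, which equals the
tie-corrected pairwise Mann–Whitney statistic (asserted against a
brute-force oracle).

## Orchestration and determinism

`run_pipeline()` executes simulate/load → normalize/filter → DE →
trajectories → DE-SWAN → lipids → PVCA → network → clock → panel, with
per-stage toggles and dependency errors when a disabled prerequisite is
needed. One master seed derives per-stage (and per-feature) seeds by a
label hash, so toggling a stage never shifts another stage's randomness.
Tables are written with 12-significant-digit formatting and the manifest
records each stage's outputs with MD5 hashes, derived seed and package
version — two runs with the same config are byte-identical, which the
acceptance suite asserts. The repository's `analysis/` scripts present
the same stages as a numbered, re-runnable workflow; they are thin
drivers over the exported functions, which is also why no separate
shell-level entry point exists.

## Numerical choices and degenerate inputs

* log offsets: half the smallest positive value by default; tests that
  need exact algebra pass an explicit tiny offset (1e-12).
* Zero-variance features: flagged and excluded from BH families and from
  curve standardization, never silently dropped.
* Spearman ties: average ranks; p by the t approximation (exact
  permutation p-values are not attempted).
* Broken-stick: knot grid step 0.1 between the second and penultimate
  x-values; the low-confidence flag fires when the slope change over the
  x-range is under 10% of the curve's spread.
* Problem sizes in the checks: the calibration suite uses 1000 null
  features at n = 136 with zero inflation disabled (the clean null for
  testing the engines' type-I behavior); clock recovery uses n = 150
  with 500 features of which 30 informative; the full-pipeline
  determinism check runs the 200-metabolite default cohort twice.

## Known limitations

Per-feature tests assume independent samples (no family structure or
repeated measures); DE-SWAN strata reuse samples across neighboring
centers, so the count curve is autocorrelated by construction and peak
p-values are not provided; PVCA's categorical age factor discards
within-group age variation; the elastic-net clock inherits the usual
instability of correlated-feature selection (two informative, correlated
features may split or swap coefficients between seeds); and the
generator's independence of features given the design means estimated
false-discovery behavior on real, correlated data can be worse than on
these fixtures.
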