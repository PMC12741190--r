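# lifespanomics

Cross-sectional plasma metabolomics and lipidomics change continuously
from birth to late adulthood: newborns carry a distinct saturated-
sphingosine signature, amino acids and bile-acid species rise steadily
with age, and the rate of metabolic change itself waxes and wanes, with
crests of differential expression at particular ages. `lifespanomics`
packages the full analysis chain for such cohorts — normalization and
filtering, group-wise differential expression, linear and LOESS age
trajectories, sliding-window differential expression (DE-SWAN), lipid
chain-length/saturation analytics, principal variance component analysis
(PVCA), metabolite–lipid correlation networks, and a multi-stage
elastic-net aging clock with broken-stick model reduction and a
cross-validated biomarker panel — together with a synthetic cohort
generator whose ground truth lets every stage be tested without access
to any real cohort.

It is aimed at metabolomics analysts who have a feature-abundance matrix
(features × samples) and per-sample age/sex/life-stage metadata and want
a tested, deterministic pipeline rather than a pile of one-off scripts.

## The models at the core

**Per-feature linear age model.** For each feature, on log10-normalized
abundance,

    y = α + β₁·Age + β₂·Sex + ε

fitted by OLS; the age term is tested with a Type II partial F-test and
p-values are BH-adjusted across features.

**DE-SWAN.** For each center *c* on the age axis, samples with age in
[c − w/2, c) and (c, c + w/2] form young/old strata (w = 20 years by
default); per feature, log10 abundance is regressed on the stratum
indicator plus sex, BH within center, and the count of q < 0.05 features
per center traces where metabolic change concentrates. Peaks are called
deterministically (local maximum within ±5 years, ≥ 2 raw MADs above the
curve median).

**Aging clock.** Elastic net (mixing α ∈ 0.1–0.9, penalty λ by 10-fold
CV) over stratified train/test splits at training fractions 0.5–0.8; the
(α, fraction, λ) with the smallest held-out mean absolute error is the
clock. Reduction refits on the top 2, 3, 4, … features (ranked by
standardized coefficient magnitude) and locates the accuracy breakpoint
by two-segment broken-stick regression. The biomarker panel is the
triple intersection {up in the elderly (≥ 65 vs < 40)} ∩ {significant
linear increase} ∩ {nonzero clock coefficient}, scored by 10-fold CV ROC.

**Lipid analytics.** Shorthand names such as `TG(16:0/18:1/18:2)` or
`SPH(d18:0)` are parsed into class, chains and double bonds; species are
classed S / MU / PU at exactly 0 / 1 / ≥ 2 double bonds, and per-group
polyunsaturated:saturated intensity ratios are averaged per sample.

## Worked example

The `analysis/` directory is a numbered workflow over the package; each
script reads the previous step's outputs from `results/analysis/`:

```sh
Rscript analysis/01_simulate_cohort.R
Rscript analysis/02_normalize_filter.R
# ... through ...
Rscript analysis/08_aging_clock.R
```

Step 1 simulates 136 subjects aged 0–84 in seven life-stage groups with
200 metabolite features (null, linear ±0.01/y, peaked at 20 and 60,
step changes at 40 and 65, newborn/elderly group markers) and a
432-species lipid panel in which saturated SPH is elevated in newborns
and polyunsaturated TGs rise with age. On this cohort the workflow
prints, among others:

```
newborn DEMs significant against all six groups: 8
most enriched kind among all-six DEMs: group_marker (q = 1.14e-08)
linear trends: 41 increase, 61 decrease, 98 ns
window 20: peaks at 10, 30, 35, 41, 65 (max n_sig = 13)
PU:S minimum in A_newborn (4.51 vs cohort mean 6.07)
after SPH exclusion the group spread is 18.8%
PVCA fractions: age=0.184 sex=0.007 age_sex=0.008 residual=0.802
metabolite clock: 98 features, test MAE 5.93 y, r 0.960 (alpha 0.1)
combined clock: 44 features, test MAE 5.58 y, r 0.973 (alpha 0.9)
reduced clock: breakpoint at 4 features (r = 0.810)
panel classifier: mean 10-fold CV AUC = 1.000
```

Read: the generator's newborn markers are recovered as newborn DEMs and
dominate the kind-level enrichment; the DE-SWAN crests sit near the
engineered step ages 40 and 65 (plus early-life trajectory bends); the
newborn group shows the minimum PU:S ratio, and removing SPH flattens
the group differences; age dominates sex in the PVCA factor fractions;
the clocks predict age to ~6 years held-out MAE, the broken stick prunes
the metabolite clock to 4 features, and the elderly-vs-young panel
separates perfectly on this synthetic signal.

The same stages can be driven in one call (with a manifest and
deterministic per-stage seeding) via:

```r
library(lifespanomics)
run_pipeline(run_config(seed = 1, out_dir = "results/run"))
```

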