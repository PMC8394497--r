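# t2asym

Contralateral signal and texture features from dual-echo T2 maps, for
studying progression from mild cognitive impairment (MCI) to Alzheimer's
disease.

## What this package is for

Quantitative T2 relaxometry measures the transverse relaxation time of
brain tissue, a property sensitive to microstructural change. A dual fast
spin-echo acquisition gives two images of the same anatomy at different
echo times — one proton-density weighted (short TE), one T2-weighted
(long TE) — from which a T2 value can be computed in closed form at every
voxel. Because early neurodegeneration is often asymmetric (hippocampus
and amygdala in particular), features that compare mirrored left/right
anatomical regions are candidate imaging biomarkers for identifying which
MCI patients will progress to dementia.

`t2asym` implements that analysis as a reusable, fully tested pipeline
for neuroimaging researchers:

1. **T2 mapping** — the two-point mono-exponential solution
   `T2(i) = (TE_b − TE_a) / (ln S_a(i) − ln S_b(i))`, with validity
   masking and physical-range clamping (`compute_t2_map`).
2. **Atlas registration** — rigid registration (Mattes-style mutual
   information, regular-step search plus simplex refinement) bringing an
   anatomical-space segmentation into T2-map space, with
   nearest-neighbour label resampling and Dice QC (`register_rigid`,
   `resample_labels`, `dice_overlap`).
3. **Regional radiomics** — a 38-feature vector per region: volume, 28
   intensity-distribution statistics (mean, dispersion, percentiles,
   central-90% statistics, histogram entropy/energy, shape-of-distribution
   and tail probabilities) and 9 texture features (the six components of
   the intensity-weighted mass-scatter tensor `M_ab = Σ w_i (a_i − c_a)(b_i − c_b)/Σ w_i`
   plus surface area, compactness `36πV²/A³` and sphericity)
   (`feature_registry`, `extract_all`).
4. **Contralateral folding** — for each of 40 mirrored region pairs and
   each of the 37 signal/texture features, the pair mean `(f_L + f_R)/2`
   and absolute difference `|f_L − f_R|`: 2960 derived columns on the
   full 83-region atlas, plus the 83 region volumes and 8
   neuropsychological scores (`fold_contralateral`, `build_feature_table`).
5. **Univariate screening** — two-sided Wilcoxon rank-sum tests per
   feature, Benjamini–Hochberg q-values within each feature family, and a
   per-family top-fraction selection pool (5% of signal/texture = 148,
   15% of volumes = 12, all neuropsych scores) (`screen_features`,
   `demographics_tests`).
6. **Multivariate benchmark** — repeated stratified 80/20 holdout (100
   repeats by default) over a grid of feature filters (Wilcoxon, t-test,
   Kendall τ-b, mRMR, LASSO path, tree importances, IDI, NRI, a
   bootstrapped stepwise surrogate) crossed with classifiers (kNN,
   L1-logistic, bagged trees, CART, linear SVM, naive Bayes, nearest
   centroids, majority-vote ensemble), reporting pooled accuracy,
   sensitivity, specificity, balanced error and ROC AUC with bootstrap
   95% CIs, and per-filter feature-selection frequencies
   (`repeated_holdout`, `run_experiments`, `selection_frequency`).

Real clinical images (e.g. ADNI) are deliberately out of scope here:
instead the package ships a **synthetic phantom cohort generator**
(`phantom_spec`, `simulate_cohort`) that emulates paired-echo volumes with
mono-exponential decay and noise, a mirrored ellipsoidal multi-region
atlas, a known rigid misalignment between echo and anatomical spaces, and
group-dependent regional T2 and asymmetry effects — so every stage can be
validated against known ground truth.

## Worked example

```r
library(t2asym)

spec <- phantom_spec(seed = 1)       # 22 stable + 18 progressors,
                                     # asymmetry planted in pair 1
pipe <- t2asym_pipeline(spec, registration = "truth")
pipe$table
#> feature_table: 40 subjects x 465 feature columns (8 neuropsych, 336 signal, 108 texture, 13 volume)
pipe$screen
#> univariate_screen: 465 features tested, 31 significant (q < 0.05), pool of 32
#> top features:
#>   pair01.mean.absdiff    p = 7.9e-08  q = 3.9e-06
#>   pair01.p25.absdiff     p = 7.9e-08  q = 3.9e-06
#>   pair01.p50.absdiff     p = 7.9e-08  q = 3.9e-06
#>   ...

cfg <- benchmark_config(n_repeats = 25, filters = c("wilcoxon", "mrmr"),
                        classifiers = c("knn", "lasso"), seed = 1)
ex <- run_experiments(pipe$table, pipe$screen, cfg)
ex$comparison[, c("method", "accuracy_np", "accuracy_np_imaging")]
#>           method accuracy_np accuracy_np_imaging
#> 1       mrmr+knn       0.740                0.97
#> 2     mrmr+lasso       0.775                0.97
#> 3   wilcoxon+knn       0.740                0.97
#> 4 wilcoxon+lasso       0.775                0.96
```

The screen output says: the contralateral absolute differences of pair-1
features (where the generator planted a 10 ms left/right T2 asymmetry in
the progressor group) dominate the ranking, with q-values far below 0.05.
The comparison table shows the pooled holdout accuracy of every
filter × classifier method improving (here from ~0.74–0.78 to ~0.97)
when the screened imaging features are added to the eight
neuropsychological scores — the paired two-experiment design the
pipeline is built to evaluate.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes the whole analysis from scratch against the installed package:
it simulates the default 40-subject phantom cohort, estimates every T2
map, applies the misalignment correction, extracts and folds the
features, runs the univariate screen and demographic tests, verifies a
per-subject rigid registration, and runs the paired
neuropsych-only / neuropsych-plus-imaging benchmark, printing each
stage's summary and writing the JSON result file.

## Layout

- `R/` — implementation (phantom, mapping, registration, features,
  folding, statistics, benchmark, pipeline)
- `tests/testthat/` — unit, property and acceptance suites with
  independent brute-force oracles
- `vignettes/t2asym-methods.Rmd` — the methods vignette: models,
  assumptions, parameter choices, limitations
- `scripts/acceptance.R` — end-to-end acceptance run
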