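---
title: "Methods: contralateral T2-map radiomics from phantom to benchmark"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: contralateral T2-map radiomics from phantom to benchmark}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(t2asym)
```

This vignette documents the models implemented by `t2asym`, the
assumptions behind them, the tunable parameters and their defaults, what
the synthetic phantom does and does not emulate, and the numerical and
design choices made where a published description left the matter open.

## 1. The two-point T2 model

A dual fast spin-echo acquisition yields two images of the same anatomy
with echo times $TE_a < TE_b$. Under mono-exponential transverse
relaxation, the signal at echo time $TE$ is $S = S_0 e^{-TE/T_2}$, so two
echoes determine the two unknowns exactly:

$$T_2(i) = \frac{TE_b - TE_a}{\ln S_a(i) - \ln S_b(i)}.$$

`compute_t2_map()` applies this voxel-wise. Three degenerate situations
are marked *invalid* rather than given a number: $S_a \le 0$,
$S_b \le 0$ (background or noise-dominated voxels), and $S_a \le S_b$
(no apparent decay; the denominator is zero or negative). Invalid voxels
carry `t2_ms = 0` and are excluded from all downstream regional
statistics — they are never imputed, and background is invalid rather
than "T2 = 0".

Noise makes the estimator heavy-tailed near $S_a \approx S_b$, so valid
values are clamped to `clip_range_ms` (default 1–3000 ms, generous
physical plausibility bounds) and stay valid. Without clamping, a single
near-singular voxel can dominate a regional histogram. The residual map
of `t2_fit_quality()` is identically zero at unclipped valid voxels
(two points determine the model exactly), so a positive residual flags
precisely the clipped ones.

**Assumptions**: mono-exponential decay (no multi-compartment T2, no
stimulated-echo or B1 correction) and additive noise. Echo times are
user-supplied; the phantom default is 10/110 ms, a plausible dual-echo
spacing that keeps both echoes informative for tissue T2 of 70–130 ms.

## 2. Rigid registration of the segmentation

Segmentation labels are defined on an anatomical (T1-type) volume
acquired in the same session, so only a small rigid transform separates
the spaces. `register_rigid()` estimates the transform that maps
fixed-space (T2-map) world coordinates into anatomical coordinates, by
maximising mutual information:

- **Metric**: a Mattes-style joint histogram (32 bins per image over each
  image's own sampled range). The interpolated moving sample is shared
  between its two nearest bins with linear (tent) weights, which makes
  the metric vary smoothly under sub-voxel motion.
- **Sampling**: a deterministic stride over a margin-padded bounding box
  around the foreground (values above 20% of the robust maximum),
  roughly 20,000 points. No RNG is involved, so registration is exactly
  reproducible.
- **Optimiser**: a regular-step coordinate search (steps halved when no
  parameter probe improves the metric) to enter the capture range,
  followed by Nelder–Mead simplex refinement.
- **Smoothing**: one pass of a separable binomial [1,2,1]/4 kernel on
  both images (`smooth_passes = 1`). Empirically this mattered: on raw
  noisy volumes the MI *optimum itself* (not the optimiser) was displaced
  by 0.6–1.6° on some noise realizations; after light smoothing the
  known phantom misalignment is recovered to ≤ 0.2 mm / 0.2°.
- **Direction**: the T2 side is fixed and the anatomical side moves, so
  the quantitative map is never resampled; labels follow the anatomical
  image with nearest-neighbour interpolation only (labels are
  categorical; no new label can be created, and out-of-grid voxels get
  background 0).
- **Channel**: registration runs on the long-echo (T2-weighted)
  intensity image by default. In the phantom, the short echo has almost
  no inter-region contrast ($e^{-10/T_2}$ varies by only a few percent
  across 70–130 ms), which degrades MI; the long echo carries the
  T2 contrast. A T2-map input is also accepted.

Failure modes are explicit: insufficient field-of-view overlap at the
initial transform (fewer than 25% of samples landing inside the moving
grid) or a non-finite metric raise errors carrying the optimisation
trace; registration never silently returns the identity.

**QC**: visual inspection is replaced by an automated per-region Dice
report (`dice_overlap`). One caveat found during development: at 2 mm
voxels, resampling a small (~140-voxel) region into the anatomical frame
and back with nearest-neighbour interpolation floors per-region Dice
near 0.77 *even with the exactly true transform* — pure quantisation,
not misregistration. Registration quality is therefore assessed by
parameter recovery (≤ 0.5 mm / 0.5°) and by Dice against the
true-transform resampling, which isolates the registration component.

## 3. The 38-feature regional vector

Each region yields 1 + 28 + 9 features (`feature_registry()`):

- **Volume**: labelled-voxel count × voxel volume, counting voxels
  regardless of T2 validity (volume is anatomical, not intensity-based).
- **28 signal features** on the valid-voxel T2 values: mean, sd,
  intensity coefficient of variation (ICV = σ/µ), skewness, excess
  (Fisher) kurtosis, histogram entropy and energy, nine percentiles
  (0.01, 1, 5, 25, 50, 75, 95, 99, 99.99), mean/sd/ICV restricted to the
  central 90% of values (within [P5, P95]), precision range (P95 − P5),
  min, max, range, median absolute deviation, and four one-sided
  mean-centred tail probabilities (below µ−2σ, below µ−3σ, above µ+2σ,
  above µ+3σ).
- **9 texture features**: the six components of the intensity-weighted
  second central moment ("mass scatter") tensor of the voxel world
  coordinates, in mm² (Y = anterior–posterior); and three mask-shape
  features — face-counted surface area, compactness $36\pi V^2/A^3$
  (1 for a perfect sphere) and sphericity (its cube root).

Interpretation choices, fixed and documented here because the exact
28-feature enumeration of the source literature is not public:

- "ICV" is read as the intensity coefficient of variation σ/µ, the only
  expansion consistent with a per-region signal statistic.
- "Probability of value lower than 2σ" is read one-sided and
  mean-centred: $P(v < \mu - 2\sigma)$; "greater than 3σ" as
  $P(v > \mu + 3\sigma)$.
- "Precision range" is P95 − P5.
- Histogram entropy (base 2) and energy ($\sum p^2$) use 64 equal-width
  bins over the region's own [min, max]; a constant region is defined to
  have entropy 0 and energy 1.
- Percentiles interpolate linearly between order statistics (R quantile
  type 7) — the convention matters below ~100 voxels.
- The mass-scatter tensor is computed on the full 3D voxel set with
  intensity weighting, the conservative reading that keeps "Mass
  Scatter YY" well-defined in mm²; a 2D-projection variant would be a
  registry extension.
- The MAD is unscaled (no 1.4826 normal-consistency factor).
- `min_voxels = 10`: a region with fewer valid voxels degrades to an
  all-NA sentinel (logged, never an error), so one failed region cannot
  abort a subject.

Every feature is verified against an independently coded brute-force
oracle to 1e−9 in the test suite, along with translation invariance and
intensity-scale behaviour (scaling T2 by $k$ scales location/dispersion
features by $k$ and leaves ICV, shape-of-distribution, histogram, tail
and all texture features unchanged).

## 4. Contralateral folding

For each mirrored pair and each of the 37 signal/texture features,
`fold_contralateral()` derives the arithmetic pair mean $(f_L + f_R)/2$
and absolute difference $|f_L - f_R|$ — the pooled-voxel alternative
(recomputing the feature on L∪R voxels) is rejected because published
per-feature "Mean" rows refer to the feature, not a voxel pool. Volumes
pass through unfolded. On the full 40-pair + 3-midline atlas this yields
exactly 37 × 2 × 40 = 2960 derived columns plus 83 volumes; both counts
are asserted in the acceptance suite. Missing policy: if either member
of a pair is missing, both derived features are missing; columns more
than 20% missing within a training fold are dropped, the remainder
median-imputed *within training folds only* (a leakage-safe choice; the
source description is silent on imputation).

## 5. Univariate screening

Each feature column is compared between stable (MCIs) and progressor
(MCIp) groups with the two-sided Wilcoxon rank-sum test: exact null
distribution when both groups have ≤ 10 tie-free observations, otherwise
the normal approximation with tie and continuity corrections (the mode is
recorded per feature). Benjamini–Hochberg q-values are computed
*within each family* — neuropsych scores, volumes, and the pooled
signal/texture set — mirroring how such studies report the families
separately; volumes are excluded from the imaging pool by default (the
most conservative reading of an ambiguous description). Degenerate
(constant) columns get p = 1 and stay in the ranking.

The multivariate selection pool is defined by family-specific top
fractions of the raw p-value ranking rather than a fixed threshold
(defaults 5% of signal/texture, 15% of volumes, all neuropsych scores),
reproducing a 148 + 12 + 8 pool on the full atlas. Demographics are
tested as published: Wilcoxon for age and education, Yates-corrected
chi-squared for the sex proportion.

## 6. The repeated-holdout benchmark

`repeated_holdout()` draws `n_repeats` (default 100) independent
stratified 80/20 splits — per group, `round(0.2 n_g)` test subjects, so
group proportions are preserved to within one subject; whether such
schemes should instead guarantee coverage of every subject is unstated
in the source, and independent random splits are used. For every
filter × classifier method the entire pipeline — median imputation,
standardization, feature filtering, model fitting — is trained on the
training split only; held-out scores are pooled across repeats.

Metrics come from the pooled out-of-sample predictions at score
threshold 0.5, with MCIp as the positive class: accuracy, sensitivity,
specificity, balanced error $1-(\text{sens}+\text{spec})/2$, and the
midrank ROC AUC. The 95% CI is a percentile bootstrap (default 2000
draws) over *subjects*, keeping each subject's pooled predictions
together; the source's exact CI construction is unstated.

Design choices in the registries:

- **BSWiMS surrogate**: bootstrapped forward stepwise logistic selection
  (B = 20 bootstraps, entry by likelihood-ratio p < 0.1, kept if
  selected in ≥ 30% of bootstraps). Entry uses the likelihood-ratio
  rather than the Wald statistic because Wald p-values collapse under
  the complete separation a strong biomarker causes. This is a
  documented surrogate, not a reimplementation.
- **mRMR**: greedy, relevance = |Kendall τ-b with the class|, redundancy
  = mean |τ-b| with the already-selected set.
- **Filters return 10 features by default**, matching the order of
  magnitude of model sizes reported for comparable tree-based pipelines
  (~10 features per model).
- **Ensemble** combines the other classifiers by majority vote (score =
  vote fraction); how published ensembles combine member scores is
  unstated, and the vote is the simplest defensible choice.
- Several learners (naive Bayes, nearest centroids, linear squared-hinge
  SVM, CART-style trees and their bagged ensemble) are implemented
  in-package because no corresponding package is available in the
  supported environment; all operate on panels of tens of subjects and
  ~10 features, where these compact implementations are appropriate.

`run_experiments()` runs the neuropsych-only and neuropsych+imaging
experiments on *identical* splits (same seed), so the imaging increment
is a paired comparison.

## 7. The synthetic phantom: what it does and does not establish

`phantom_spec()` fixes the simulated world:

- 64 × 64 × 48 grid, 2 mm isotropic; 6 mirrored ellipsoidal pairs
  (semi-axes 8 × 6 × 6 mm) plus 1 midline region. The full-scale
  40 + 3 = 83-region layout is a configuration preset used for
  manifest-count checks; the desk-scale default keeps property suites
  fast. The mid-sagittal plane is the grid centre along x; left = lower
  x; right-hemisphere regions are voxel-exact mirrors of the left.
- Baseline regional T2 spans 70–130 ms; per-subject pair-level
  variation 4 ms sd (both sides equally), natural left-right asymmetry
  2 ms sd. S0 = 1000 ± 50 between subjects; additive Gaussian noise of
  sd 10 (1% of S0) per echo, chosen for testability — real acquisition
  noise levels for these sequences are not published. A magnitude-Rician
  option exists.
- Group effects: progressors receive, in pair 1 (the "hippocampus
  analogue"), a +6 ms bilateral shift and a 10 ms *pure* asymmetry,
  split antisymmetrically (+5 left, −5 right) so it widens |L − R|
  without moving the pair mean — a unilateral shift would mostly load on
  the pair-mean features and would not emulate an asymmetry biomarker.
- A known rigid misalignment (2 mm x, 2 mm y, 3° about z) maps the
  anatomical frame to the echo frame; its inverse is stored as ground
  truth for the registration tests.
- Neuropsych scores are Gaussian with group mean shifts on the memory
  composite and ADAS-11 only (the two scores that typically separate
  MCI groups); cohort demographics (ages 70–80, education, 32/40 male)
  match the motivating cohort's Table-1 profile, with 22 stable and 18
  progressor subjects.

The phantom deliberately omits realistic anatomy, partial-volume
effects, bias fields, and multi-site scanner variation. A green test
therefore establishes that the *pipeline machinery* is correct —
estimators recover planted truth, no stage leaks test information,
counts and identities hold — not that the published clinical effect
sizes are reproduced; those require the original clinical images, which
are out of scope.

## 8. Known limitations

- Two-echo T2 only; no multi-echo least-squares fit.
- Rigid registration only; capture range is a few degrees/mm (adequate
  for same-session motion).
- The 28-signal-feature registry is a reconstruction; `paper_named`
  flags in `feature_registry()` separate explicitly published names from
  symmetric fill-ins, and the registry is configurable.
- Exact Wilcoxon mode switches to the normal approximation above n = 10
  per group or under ties; near the boundary the two differ by up to
  ~0.011 in p (measured), which is immaterial for ranking but recorded.
- GLCM/GLRLM/wavelet radiomics and full IBSI compliance are out of
  scope.
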