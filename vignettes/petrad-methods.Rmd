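---
title: "Amino-acid PET radiomics for recurrent brain tumor versus radiation necrosis: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{petrad methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

After radiotherapy for glioma or brain metastasis, treatment-induced
radiation necrosis mimics tumor recurrence on contrast MRI. Amino-acid
(methionine) PET helps separate the two: the conventional reading is the
tumor-to-normal-cortex ratio (T/N), the lesion SUVmax divided by the
SUVmean of the contralateral normal frontal cortex. `petrad` implements a
complete radiomics alternative — threshold segmentation, fixed-bin
gray-level discretization, a 42-feature texture panel, SMOTE-balanced
random-forest classification with repeated stratified 10-fold
cross-validation and mean-decrease-Gini importance — together with the
T/N comparator and the shared diagnostic-evaluation machinery, and a
synthetic brain-PET phantom generator that makes the whole pipeline
testable without clinical images.

# Segmentation

The cortex reference is the arithmetic mean of SUV over voxel centers
inside a 1.0-cm^3 sphere (radius 6.20 mm). The lesion VOI is the set of
voxels inside a user seed sphere with SUV *strictly greater* than 1.3
times that reference; of the super-threshold voxels we keep the
26-connected component containing the hottest voxel. The choice of
component rule is ours: the clinical procedure only requires that a sphere
"encompass" the target lesion, and keeping the hottest-voxel component is
deterministic and matches visual practice. Cases with an empty thresholded
mask count as lacking definite abnormal uptake; non-empty VOIs of at most
64 voxels (inclusive) are excluded as too small for texture analysis; the
rest are kept. "Within a sphere" always means the voxel center lies within
the radius — an unambiguous, resolution-independent rule. World
coordinates are mm; manifests never carry voxel indices.

# Discretization and the feature panel

SUV is resampled onto 64 gray levels over the absolute range 0–20 SUV.
The bin width uses the `(levels - 1)` convention,
`20 / 63 = 0.3175 ≈ 0.317`; the `(levels)` convention (0.3125) is
selectable. Level assignment is
`clamp(1 + floor((x - min) / bin), 1, 64)`, monotone in SUV, with values
at or above the upper bound mapped to the top level.

The full computed panel has 45 names; the default active registry has 42:
the two log10 entropy variants and the compacity shape descriptor are
toggled off (their log2 and sphericity counterparts remain). Families and
conventions:

* **Conventional**: SUVmin/mean/max, population SD, MTV (mL),
  TLG = SUVmean × MTV.
* **Histogram**: skewness and kurtosis of the level distribution
  (population moments; kurtosis non-excess, normal = 3; both reported as 0
  for a constant region), entropy (log2 and log10), energy.
* **Shape**: sphericity `π^(1/3) (6V)^(2/3) / A` and compacity
  `V / (√π A^(3/2))`, with A the voxel-face surface area (faces between
  in-mask and out-of-mask voxels, including grid boundaries). Face-count
  area overestimates a smooth surface by up to 3/2, so the sphericity of a
  large digitized ball plateaus near 2/3 rather than 1; we keep the
  estimator because it is exact for the unit-cube closed form and
  monotone for elongation comparisons.
* **GLCM**: co-occurrences at distance 1 over the 13 unique 3-D
  directions, both voxels in-mask, counted symmetrically, pooled into one
  matrix and normalized (a per-direction averaging mode is available).
  Features: homogeneity, energy, contrast, correlation (defined as 0 with
  a warning when the gray-level variance is 0), entropy (log2/log10),
  dissimilarity.
* **GLRLM**: maximal same-level runs along each of the 13 directions,
  pooled. Run percentage divides the run count by `13 × Nv` (each voxel
  counts once per direction).
* **GLZLM**: zones are 26-connected equal-level components; features
  mirror the run-length formulas; zone percentage is zones over `Nv`.
* **NGLDM**: for each masked voxel, the absolute difference from the mean
  level of its in-mask 26-neighbors (voxels with no in-mask neighbor
  contribute 0). Coarseness is the inverse probability-weighted difference
  sum with the denominator floored at 1e-6 (so a perfectly homogeneous
  region returns the finite maximum 1e6 and every feature stays finite);
  contrast and busyness use the standard neighborhood-difference
  definitions with degenerate single-level or zero-denominator cases
  mapped to 0.

Every texture family is validated against an independent brute-force
oracle (per-voxel neighbor scans, explicit line walking, stack-based flood
fill) to 1e-10 relative error on randomized small masks.

# Classification

Features are centered and scaled (sample SD; constant columns pass through
with a warning). Class imbalance (33 recurrence vs 11 necrosis) is
addressed by SMOTE: synthetic minority rows are convex combinations
`x + u (x_nn − x)`, `u ~ U(0,1)`, of a minority row and one of its five
nearest minority neighbors in the standardized space, up to equality with
the majority. The forest (the `randomForest` implementation) uses the
printed operating point ntree = 100, mtry = 1 by default, with the tuning
grid (100, 250, 500, 750, 1000, 1500) available through `tune_forest()`
(arg-max of mean repeated-CV accuracy, ties to the smaller ntree).

Cross-validation is stratified 10-fold, repeated (10 evaluation repeats,
100 tuning repeats by default). Two SMOTE placements are provided because
the wording of the original analysis suggests balancing *before*
cross-validation, which leaks synthetic copies of test lesions into
training folds and inflates apparent performance: the default
`inside_cv` standardizes and SMOTEs the training folds only (leak-free);
`before_cv` balances the whole cohort first and is flagged in every
report it touches. Hard labels use the 0.5 probability threshold; ROC
analysis uses the continuous out-of-fold probability. Confusion metrics
are averaged over repeats as per-repeat fractions (not pooled counts) —
the aggregation the package uses everywhere. Splitting is by lesion;
with multiple lesions per patient a by-patient split would be a
conservative alternative. Importance is the mean decrease in Gini
impurity of the forest fitted on the full balanced cohort.

# Evaluation

`roc_auc()` computes AUC as the tie-aware rank statistic
(`P(score_pos > score_neg) + 0.5 P(tie)`), the curve by sweeping all
distinct scores with the rule `score >= cutoff ⇒ positive`, and the
operating cutoff by maximizing Youden's J with ties resolved toward the
lower cutoff. The identity `AUC · n1 · n2 = U` against the Mann-Whitney
statistic is enforced by test. The Mann-Whitney test is exact (via
`wilcox.test`) for tie-free samples with at most 12 observations
combined, otherwise the normal approximation with tie and continuity
corrections; Spearman correlation is the mid-rank Pearson correlation
with the t approximation. Group comparisons report medians and
interquartile ranges (linear-interpolation quartiles, type 7) per class
with raw p-values at 0.05, mirroring the clinical table; a
Benjamini-Hochberg option exists but is off by default. The positive
class is recurrence throughout.

# The phantom generator

No clinical images are deposited, so the cohort is synthetic. Each
phantom is a 64^3 grid at 2 mm isotropic (brain-scale field of view at
PET resolution): background SUV 1.0 with 0.1 pre-smoothing variation, a
cortex ball (radius 10 mm) contralateral to the lesion whose level is
drawn per case from U(1.35, 1.58) SUV (between-patient variation in
global cortical methionine uptake), and one lesion — a spherical plateau
with a 3-mm Gaussian infiltrative margin, modulated by a multiplicative
Gamma texture field (mean 1, SD = amplitude, correlation length 2 mm,
generated through a Gaussian copula so that texture strength is monotone
in the amplitude under a fixed seed). The scene is smoothed with the
5-mm FWHM Gaussian post-filter of the clinical protocol, then
independent Gaussian noise (SD 0.05 SUV) is added and values are clamped
at 0.

Class-conditional draws: contourable lesions are parameterized by their
tumor-to-cortex ratio target — recurrence U(1.75, 2.45) with
heterogeneity amplitude U(0.30, 0.50) and radius U(11, 14) mm; necrosis
U(1.75, 2.25), amplitude U(0.02, 0.06), radius U(10, 13) mm. Because the
hot tail of the texture field inflates the post-smoothing maximum by
about `1.06 (1 + 1.2 × amplitude)` under this geometry, that factor is
divided out of the plateau so the SUVmax distribution follows the drawn
target rather than the texture strength; a plateau floor of 1.45× the
cortex level keeps every contourable lesion well above the 64-voxel
exclusion. This decoupling is what lets the phantoms reproduce the
clinical situation in which SUVmax (and hence T/N) separates the classes
only weakly while texture separates them well. The excluded strata use
absolute targets: "no definite uptake" lesions peak below 1.25 SUV, far
under any threshold; "subthreshold" lesions are small hard-edged hot
foci (plateau 4.2–4.6 SUV, radius 3.4–4.0 mm) whose thresholded VOIs
stay within 64 voxels. The default cohort is 33/11/5/3 = 52 candidates,
of which exactly 44 survive the exclusion rules.

With these defaults, cohort medians land near the clinical values —
SUVmax ≈ 3.3 vs 2.8 (clinical 3.0 vs 2.7), GLCM dissimilarity ≈ 0.69 vs
0.46 (clinical 0.65 vs 0.40) — and their ordering, the strong positive
correlation between T/N and dissimilarity, and the direction of the
radiomics-vs-T/N comparison are reproduced. The magnitudes of the
diagnostic metrics are not: phantom cohorts are easier than patients
(the forest's out-of-fold AUC is near 1 and the phantom T/N AUC is
higher than the clinical 0.73), and passing tests on phantoms says
nothing about clinical accuracy — only that the pipeline measures what
it claims to measure. Other deliberate simplifications: no scanner or
reconstruction model, a single lesion per volume, spherical geometry,
stationary texture, no partial-volume correction, no inter-reader
variability.

# Numerical choices and problem sizes

Gaussian smoothing is separable with replicate (clamped-index)
boundaries, exactly equal to dense convolution with the outer-product
kernel (kernels truncated at 4 sigma and renormalized); a dense
triple-loop oracle checks it to 1e-6. Discretization guards the upper
bound explicitly against floating-point rounding. Determinism: every
stochastic stage derives its stream from integer seeds through a
multiply-mod scheme (all seeds below 2^31), so cohorts, folds, SMOTE and
forests reproduce bit-identically; pipeline artifacts (CSV/JSON)
re-generate byte-identically under a fixed configuration.

Test-suite problem sizes are chosen for a single CPU: texture oracles run
on 200 random masks of side at most 6; the classifier properties use 100
planted-signal seeds and 1000 null-simulation seeds (type-I error checked
per feature against a 99.9% binomial band around 0.05, the level chosen
because 42 features are tested jointly); the phantom-level comparison
uses 20 default cohorts with 10-repeat cross-validation, and the
pairwise heterogeneity ordering uses 100 seeded phantom pairs.

# Known limitations

The exact membership of the clinical 42-parameter panel is not published;
the registry here is a documented reconstruction, configurable if a
different panel is preferred. The tabulated magnitudes of scaled features
(for example low-gray-level emphases printed with 10^2 multipliers) are
display conventions we do not chase numerically. The face-count surface
estimator biases sphericity for large smooth objects, as noted. The
before/after-CV SMOTE ambiguity of the source analysis cannot be resolved
from the text; both modes are provided and labeled.
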