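---
title: "Methods: feature stability across CT acquisition settings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: feature stability across CT acquisition settings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radstab)
```

## The problem

Radiomic features — quantitative descriptors of intensity, shape and
texture extracted from a segmented lesion — are only useful as biomarkers
if they survive the ordinary variability of clinical imaging. CT
reconstruction choices (slice thickness, matrix, convolution kernel) and
even the export route (scanner console vs. PACS) perturb voxel data and
therefore the features computed from it. `radstab` implements a complete
workflow for quantifying that perturbation and its downstream effect on
malignancy classifiers for pulmonary nodules:

1. simulate nodule volumes (or feature panels) under ten acquisition
   settings, one parameter varied at a time from a reference acquisition;
2. extract a reduced IBSI-style radiomic feature set;
3. stratify features by a two-way mixed-effects, absolute-agreement
   intraclass correlation (ICC) across settings;
4. train stability-stratified malignancy models and measure how their
   performance varies across the simulated settings.

Because clinical multi-reconstruction CT archives are rarely shareable,
every stage is exercised end-to-end on synthetic data with known ground
truth; the generators are first-class, tested code.

## Acquisition settings and their image operators

`acquisition_settings()` enumerates the ten variants S1–S10. S2 is the
reference (1 mm slices, 1024×1024 matrix, B_SHARP_C kernel, console
export); every other setting changes exactly one parameter. The operators
in `apply_setting()` are deliberately simple, deterministic surrogates for
reconstruction physics (physical projection/reconstruction simulation is a
non-goal):

* **Slice thickness k ∈ {3, 5} mm** — non-overlapping k-slab averaging
  along the axial axis. This is the partial-volume effect in its purest
  form and, as in real data, the most destructive perturbation. A trailing
  slab not divisible by k is averaged over its remaining slices. The mask
  follows by nearest neighbour (central slice of each slab).
* **Matrix 512 vs 1024** — in-plane 2×2 block-mean downsampling (linear
  information loss of the coarser grid); mask takes the lower-index voxel
  of each block (a fixed nearest-neighbour tie-break).
* **Convolution kernel** — the six proprietary kernels are modelled as a
  one-parameter blur/sharpen family that preserves their ordinal
  soft-to-sharp structure: Gaussian in-plane blur of σ = 0.7 / 0.5 /
  0.3 mm (B_VSOFT_A, B_SOFT_F, B_SOFT_C), identity (B_SHARP_C, the
  reference), unsharp masking of amount 0.2 / 0.5 (B_SHARP_A, B_VSHARP_D).
  The strengths were fixed once so the simulated per-group stability
  ordering reproduces the qualitative clinical finding (slice thickness
  most destructive, transmission least); they are configurable via the
  `kernels` argument and are a stand-in, not a claim of fidelity to any
  scanner's modulation transfer function.
* **PACS transmission** — a 12-bit quantization round-trip (rounding to
  integer HU in [−1024, 3071]), i.e. a near-identity, matching the
  observation that storage-and-transfer leaves almost all features stable.

## The phantom cohort generator

`make_phantom_cohort()` embeds blob-like nodules (ellipsoids with a smooth
random surface-irregularity field) in noisy lung-window background at the
reference geometry (0.5 mm in-plane / 1 mm axial). Defaults, chosen once:

* equivalent-sphere diameters: truncated normal, mean 9.31 mm, sd 4.90 mm,
  truncated to the 5–30 mm inclusion window typical of nodule studies;
* background −800 HU with Gaussian noise sd 25 HU; nodule −50 HU — a
  plausible lung-window contrast for solid/subsolid nodules;
* benign nodules carry mild iid texture (sd 15 HU); malignant nodules
  additionally receive a smooth intensity-heterogeneity field of amplitude
  30 HU × `malignant_texture_effect`, emulating the greater textural
  heterogeneity of malignant lesions.

One master seed fans out deterministically to per-nodule child seeds, so
cohorts are exactly reproducible. What the phantom does *not* emulate:
scanner noise spectra, beam hardening, vasculature and pleural
attachments, realistic nodule margins (spiculation), or segmentation
error. Passing tests on phantoms therefore demonstrate the *pipeline's*
correctness and the *direction* of setting-induced instability, not
clinical effect sizes.

## The feature-panel generator

When imaging is unnecessary, `simulate_feature_panel()` simulates feature
tables directly under the variance-component model

x_isf = t_if + c_f z_i + δ_sf + σ_wf g_s e_isf,

with between-subject effects t ~ N(0, σ_b²), malignancy shift c_f, fixed
per-setting offsets δ, and within-subject noise. σ_w is solved per feature
so the population ICC(A,1) equals the requested target (the rater mean
square of the offsets enters the denominator, so offsets count against
absolute agreement, as they should). Optional per-setting noise scales g_s
— normalised to mean square 1 so the ICC target is preserved — let harsh
settings degrade features more than gentle ones. This extension exists
because a *constant* per-setting offset cannot change a model's AUC (AUC
is invariant to shifting all scores), so cross-setting performance
variability requires per-setting noise inflation.

`simulate_stability_scenario()` builds the constructed-truth study used in
the tests: three 40-feature blocks with target ICC 0.95 / 0.6 / 0.2, the
malignancy signal (0.3 sd per feature) placed **only** in the stable
block, and per-setting noise scales that make thick slices and extreme
kernels harsh. The per-feature effect is intentionally small — single
radiomic features are weak classifiers — so the 20-feature model reaches a
moderate AUC rather than a ceiling. The test cohort defaults to 200
subjects (larger than a typical surgical test set) so that per-setting
AUCs, and hence cross-setting AUC ranges, are estimated with useful
precision.

## Feature extraction

`extract_all()` mirrors the standard radiomics stack in a reduced,
fully-documented form (644 features by default):

* **Preprocessing** — intensities min-max rescaled to [0, 2048] over the
  whole volume (a constant volume maps to the lower bound); resampling to
  1 mm isotropic by separable cubic-spline interpolation for the image
  (clipped back to the range) and nearest neighbour for the mask; an ROI
  that vanishes under resampling raises an explicit degenerate-ROI error.
* **Discretization** — fixed bin width 25 with edges anchored at
  multiples of 25 from 0, then shifted so the lowest occupied bin is 1;
  values spanning [0, 2048] occupy at most 82 bins. Anchored edges make
  discretization reproducible across ROIs.
* **Families** — 14 shape, 18 first-order and 24 grey-level co-occurrence
  (GLCM) statistics on the original image; first-order + GLCM recomputed
  on 14 derived images: 8 undecimated single-level coif1 wavelet sub-bands
  (undecimated so sub-bands stay congruent with the mask), 3
  Laplacian-of-Gaussian scales (σ = 1, 2, 3 mm, scale-normalised), and
  the square / square-root / exponential maps with range-preserving
  scalings (the square map inverts the square-root map exactly). Shape is
  computed once, on the original mask. GLRLM/GLSZM/NGTDM/GLDM families are
  deliberately omitted: GLCM suffices to exercise stability and modelling,
  and exact parity with any third-party extractor is a non-goal.

Numerical conventions worth knowing:

* Surface area and mesh volume come from a marching-tetrahedra isosurface
  of a mildly Gaussian-smoothed (σ = 0.8 voxel) indicator field with
  linearly interpolated crossings. Smoothing anti-aliases the voxel
  staircase: a digitized 10 mm sphere scores sphericity 0.98–0.99 instead
  of ~0.76 on the raw staircase mesh. The cost is a low bias of MeshVolume
  for very small ROIs; VoxelVolume is the unbiased size measure.
* Maximum3DDiameter is the largest pairwise distance between
  boundary-voxel centres (simpler and deterministic; slightly below a
  mesh-vertex convention).
* Degenerate statistics are explicit `NA` sentinels, never silent zeros:
  skewness/kurtosis of a constant region, GLCM correlation and Imc1 of a
  single-level ROI, sphericity of a single voxel.

## Stability analysis

`icc_a1()` implements the McGraw–Wong single-rating, absolute-agreement,
two-way model,

ICC(A,1) = (MSR − MSE) / (MSR + (k−1) MSE + (k/n)(MSC − MSE)),

from the two-way ANOVA mean squares (subjects × settings). The exact
MS-based form is fixed here for reproducibility; the model family admits
several estimators and published analyses typically name only the family.
Absolute agreement is essential: a setting that shifts every nodule's
feature by a constant must be penalised. Negative estimates are retained
as computed. Zero-variance (degenerate) features are flagged and assigned
to the unstable stratum — a feature constant across patients carries no
discriminative signal and must not enter the stable model silently.

Thresholds are inclusive exactly as conventionally stated: stable
ICC ≥ 0.8, unstable ICC ≤ 0.4, intermediate in between.
`stability_by_group()` evaluates each parameter group on the settings
that isolate it (slice {S2,S3,S4}, matrix {S2,S10}, kernel {S2,S5–S9},
transmission {S1,S2}), always anchored at the reference;
`intersect_categories()` reports the cross-group Venn regions. For
*model* stratification, `stability_partition()` computes the ICC across
all supplied settings jointly — the strata should reflect overall
robustness, not any single parameter; the per-group plan remains available
and configurable for the descriptive analyses. Missing subjects are
handled by complete-case removal with a logged count (matrices must be
complete).

## Classification models

Seven models are trained per fold: FULL, S, U, I and the ablations SI,
SU, UI.

* **Normalization** — z-scores with training-fold parameters only;
  validation and test tables are never allowed to contribute their own
  means or sds. Constant features are dropped with a warning.
* **MRMR** — greedy forward selection of 20 features. Relevance is the
  one-way F statistic against the label, normalised by the maximum F among
  candidates so that relevance and redundancy (mean |Pearson| correlation
  with already-selected features) live on the same [0, 1]-ish scale; the
  criterion is their difference. This variant needs no discretization or
  binning choice, making selection fully deterministic (ties break by
  column order). Selection runs inside each fold — the leakage-safe
  default; published pipelines do not always say which they did.
* **Firth logistic regression** — maximises the Jeffreys-penalized
  likelihood ℓ(β) + ½ log det(XᵀWX) by IRLS with hat-diagonal-adjusted
  responses, at most 100 iterations ("one epoch" is read as one IRLS
  update), convergence at penalized-score norm < 1e-6, with step-halving.
  The penalty guarantees finite coefficients under complete separation —
  a real concern with 20 selected features and small folds. Collinear
  columns are dropped by pivoted QR (keeping the earlier column).
  A `penalty_weight` near 0 recovers the ordinary MLE and is used as a
  diagnostic cross-check against `glm()`.
* **Decision threshold** — 0.5, with the boundary counted positive; the
  convention is fixed so McNemar comparisons are reproducible.

## Evaluation

Metrics: AUC (midrank Mann–Whitney), accuracy, sensitivity, specificity,
G-mean = √(sensitivity × specificity) and F1. Paired model comparisons on
the reference test setting use the DeLong placement-value z-test for AUCs
(zero-variance differences return p = 1 with a flag rather than erroring)
and McNemar tests on correctness vectors, computed separately on positives
(sensitivity) and negatives (specificity): exact binomial when the
discordant count b + c < 25, continuity-corrected chi-square otherwise —
the switch point is fixed here because published analyses rarely state the
flavour. Comparisons are computed per fold (the default; pooled scores
across folds mix models fitted on different data). Significance is 0.05
two-sided without multiplicity correction, matching common practice; Holm
adjustment can be applied downstream to the emitted p-values.

Cross-validation is stratified by label with a recorded seed, five folds.
`generalizability_summary()` reduces the report to each model's min / max
/ range of fivefold-mean AUC across the per-setting test sets; the most
consistent model is the one with the smallest range.

## Pipeline, determinism and problem sizes

`run_pipeline()` ties the stages together from a JSON/list configuration
(defaults: thresholds 0.8/0.4, 20 features, 5 folds) and writes CSV/JSON
artifacts plus a manifest of md5 checksums; identical configuration and
seed reproduce identical checksums, which the test suite asserts. The
test suite and acceptance script deliberately run at desk scale: panels of
60–1000 subjects, phantom cohorts of up to 16 nodules for image-based
stability, a constructed-truth scenario of 400 training / 200 test / 200
stability subjects, 50 replicates for coefficient recovery. These sizes
were chosen to give stable Monte-Carlo estimates (ICC within ±0.02 at
n = 1000; AUC standard errors ≈ 0.03 at n = 200) while keeping a full run
in minutes on one CPU.

## Known limitations

* The setting operators are phenomenological; they reproduce directions
  and ordinal strengths of real reconstruction effects, not their
  magnitudes. In particular the simulated matrix change is harsher than
  the simulated kernel changes, whereas clinical reports place kernels
  slightly above matrix in instability.
* The reduced feature set (644) exercises the same stability machinery as
  a full extractor but per-family stability fractions are not comparable
  to panels that include GLRLM/GLSZM/NGTDM/GLDM or two-level wavelets.
* MeshVolume is biased low for sub-5-voxel ROIs (surface smoothing);
  single-voxel ROIs return sentinel values by design.
* ICC confidence intervals, alternative agreement indices (CCC,
  Bland–Altman) and calibration analyses are out of scope.
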