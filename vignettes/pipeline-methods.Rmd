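---
title: "Methods: automated MRI-based cirrhosis classification with serum fusion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: automated MRI-based cirrhosis classification with serum fusion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem and the pipeline

Cirrhosis — end-stage liver fibrosis, stage S4 in the modified-Scheuer
(Beijing) staging — is conventionally confirmed by histopathology. Serum
indices (FIB-4, APRI) are noninvasive but only moderately accurate, and
radiologist assessment of routine MRI has limited sensitivity. `hepascan`
re-implements, as a tested R package, a fully automated diagnostic pipeline
that combines a deep slice-stack classifier on pre-contrast T1- and
T2-weighted liver MRI with age and eight serum biomarkers:

1. **phantom** — a seeded synthetic cohort generator standing in for
   patient data (none are public);
2. **preprocess** — rigid co-registration to the portal-venous frame,
   liver-mask-driven slice selection, intensity clipping, padding, resizing,
   min-max normalization, and online training augmentation;
3. **cnn** — a ResNet-18 binary classifier trained with fivefold
   cross-validation; the case score is the average of the five fold models'
   sigmoid outputs; Grad-CAM activation maps for interpretation;
4. **serum** — FIB-4 and APRI comparator indices;
5. **fusion** — a random forest combining the CNN probability with the
   clinical panel, after VIF-based multicollinearity screening and
   Gini-importance feature selection;
6. **evalstats** — ROC/AUC with DeLong variance, Youden cutoffs,
   confusion-matrix metrics with exact binomial CIs, the paired tests
   (DeLong, McNemar, Kosinski weighted generalized score), calibration
   tables and decision-curve analysis;
7. **cli** — `simulate / split / train / evaluate / report` commands over a
   YAML config.

No deep-learning or random-forest runtime exists in the supported R stack,
so both the ResNet-18 engine (C++/Armadillo, float32, im2col + GEMM) and the
random forest (C++, CART with Gini splits) are implemented inside the
package and validated against independent oracles in the test suite.

# The phantom: a stated world, not a dial

Each case carries three axial sequences (`T1pre`, `T2`, `PV`), a binary
liver mask in the `PV` frame, and a serum panel. The default grid is
32 x 64 x 64 voxels (z, y, x; 5 x 1.5 x 1.5 mm) — a desk-scale stand-in,
not a realistic MR simulation (no Bloch equations, coils or bias fields).

**Geometry.** The liver cross-section is a star-convex blob: a superellipse
(exponent 2.5, mild anisotropy) modulated by low-order Fourier terms
(k = 2, 3, amplitudes up to 5%) for inter-case shape variation. Cirrhosis
adds high-order Fourier terms (k = 8..14) whose coefficient L2 norm equals
`nodularity_amp` (a fraction of local radius) — the surface-nodularity
radiological sign. The spleen is a separate blob whose cross-section area is
scaled by `spleen_ratio` in cirrhotic cases (splenomegaly); the body is an
ellipse. The through-plane profile tapers elliptically.

**Texture.** Parenchymal heterogeneity is a per-slice Gaussian random field
(white noise blurred with a Gaussian kernel of sigma 4/sqrt(2) px, i.e.
correlation length about 4 voxels), standardized and scaled to SD 0.06
inside liver and spleen; cirrhotic cases multiply that SD by
`texture_sigma` (default 1.5).

**Misalignment.** `T1pre` and `T2` are shifted by uniform integer voxels up
to `misalign_max` in-plane (1 through-plane); the mask and `PV` define the
reference frame. Integer shifts keep the phantom crisp and make
registration recovery exactly checkable.

**Biomarkers.** Conditional on class, analytes are independent
(log-normal; age Gaussian). Defaults (medians, class 0 vs 1): platelet 210
vs 105 x 10^9/L, albumin 44 vs 37 g/L, AST 34 vs 62 U/L, ALT 38 vs 50 U/L,
ALP 82 vs 110 U/L, GGT 38 vs 85 U/L, bilirubin 13 vs 21 umol/L, INR 1.03
vs 1.22, age 50 vs 55 y. The directions follow the standard clinical
picture (portal hypertension, synthetic failure, hepatocellular damage,
cholestasis, coagulopathy); the magnitudes are package defaults chosen to
be plausible for a surgical chronic-hepatitis cohort — the source study
publishes no distribution parameters, so these are *not* claimed to match
any published table. Independence conditional on class is deliberate: it is
the simplest structure sufficient to exercise selection; the VIF > 5 path
is exercised separately by duplicated-feature fixtures.

Labels are assigned by stratified shuffling with exactly
`round_half_up(prevalence * n)` positives (default prevalence 0.65,
matching the published cohort's 65%); stage is 4 for positives, uniform on
0..3 otherwise.

**What a green test does and does not establish.** The phantom's class
signal lives exactly where the model looks (mask shape, spleen size,
texture), so end-to-end recovery tests establish that the plumbing —
preprocessing, channel layout, training loop, ensembling, fusion — is
wired correctly and that a learnable signal propagates to an honest
held-out AUC. They establish nothing about real-world diagnostic accuracy:
real cirrhosis signal is subtler, correlated with confounders, and not
mask-encoded. The null-phantom test (all effect knobs off) guards against
leakage: the out-of-fold AUC must be statistically indistinguishable from
0.5.

# Preprocessing

* **Registration** (`register_rigid`): the learned registration network of
  the source pipeline is supplementary-only and out of scope; a classical
  intensity-based rigid search substitutes. The integer-translation
  correlation surface is computed in one 3-D FFT per rotation candidate
  (coarse pass), then exact zero-filled NCC is maximized over a +-1 voxel
  neighborhood (fine pass); the identity is always a candidate, so the
  reported NCC can never fall below the unregistered alignment. Images are
  resampled linearly, masks by nearest neighbor.
* **Slice selection** (`select_slices`): center = axial slice with the
  largest liver area (lowest index on ties); with N = number of
  mask-intersecting slices, offsets are `round_half_up(0.15 N)` and
  `round_half_up(0.25 N)` above and below, clamped to the mask range;
  duplicates after clamping shift inward until distinct. "15 and 25% of
  the slice numbers" is interpreted relative to the liver-spanning slice
  count N (the stated rule qualifies it "within the liver region"), not
  the whole volume.
* **Normalization** (`preprocess_stack`): per sequence, intensities are
  clipped at the volume-wise 99.9th percentile (per volume, not per slice,
  to preserve inter-slice contrast); the five slices are zero-padded
  symmetrically to square (aspect ratio preserved), resized (bilinear
  images / nearest-neighbor masks), and the five-slice image group is
  min-max scaled jointly so a single `(min, max)` pair per sequence keeps
  relative slice brightness. Whether the original pipeline normalized per
  slice or per volume is unstated; this choice is documented, not inferred.
* **Mask as channel**: the mask enters as a separate channel rather than
  being multiplied into the image — activation maps of the source model
  highlight extra-hepatic structures (spleen), which multiplication would
  discard.
* **Augmentation** (`augment`): rotation, zoom, gamma contrast, Gaussian
  noise, elastic distortion, each applied with probability 0.5, with
  geometric parameters shared between the image and mask channels of a
  slice (masks re-binarized). Magnitudes are unspecified in the source;
  defaults are mild (+-10 deg, zoom 0.9-1.1, gamma 0.8-1.25, noise SD 0.01,
  elastic 2 px). Never applied at inference; disabled in the desk-scale
  profile.

Channel layout is fixed and recorded: sequence-major, slice-minor, image
before mask — `T1pre.s1.image, T1pre.s1.mask, ..., T2.s5.mask` (20
channels for the default two-sequence model).

# The CNN

`build_model()` is a standard ResNet-18: 7x7/2 stem convolution (widened to
the input channel count), BatchNorm + ReLU, 3x3/2 max-pool, four stages of
two basic blocks (64/128/256/512 channels, stride-2 projection shortcuts at
stage entries), global average pooling, dropout, and a single-logit sigmoid
head. For 3 input channels the trainable parameter count is 11,177,025 —
the published architecture with a 1-unit head — asserted in the suite
against independent layer-by-layer arithmetic.

Training (`train_fold`) follows the stated recipe: Adam at initial LR 1e-3,
weight decay 1e-5, batch size 32, dropout 0.3, binary cross-entropy, LR
reduced on plateau of the validation AUC, early stopping, and retention of
the best-validation-AUC weights. The plateau factor (0.5), patiences
(LR 10 / stop 30 at parity scale) and minimum LR (1e-6) are not published;
the source reports a manual search, which is not reproducible, so
conventional configurable defaults are used. The desk-scale `ci` profile is
64-px inputs, at most 60 epochs, patiences 5/10; the `parity` profile keeps
512 px and 500 epochs for completeness but is never exercised by tests.
Whether the source initialized from pretrained weights is unstated; this
implementation trains from He-normal initialization.

`crossval_train` assigns stratified folds from the config seed; each case
receives exactly one out-of-fold probability (a partition property the
suite asserts), and `predict_proba` averages the five fold sigmoids.

**Aggregation caveat.** Out-of-fold probabilities are the right *features*
for the fusion stage and the right per-fold validation metric, but pooling
raw out-of-fold probabilities across folds into one AUC is scale-sensitive:
once fold models saturate, each fold's probabilities live on a slightly
different scale, and the pooled ranking can degrade even when every fold
ranks its own cases perfectly. Held-out performance is therefore always
measured the way the source pipeline does: a separate testing split scored
with the ensemble-averaged probability.

**Numerics.** The engine is float32. Given a fixed seed the run is
bit-reproducible on one machine (own mt19937 streams for init, shuffling
and dropout); across BLAS builds, traces may differ at ~1e-6 and the
documented reproducibility tolerance for validation-AUC traces is 1e-6.
Gradient correctness is tested by directional finite differences on layers
whose difference path avoids max-pool kinks (float32 difference quotients
cannot resolve the others; the package's analytic gradients are exact up to
float rounding everywhere).

`gradcam` implements standard Grad-CAM: channel weights are spatially
averaged gradients of the cirrhosis logit at a chosen stage, the heat map
is the ReLU of the weighted feature-map sum, bilinearly upsampled to input
size. At 32-px test inputs stage 4 collapses to 1x1, so localization tests
read stage 2; at 512 px the conventional last stage is informative.

# Serum indices

`fib4(age, ast, platelet, alt) = age * AST / (platelet * sqrt(ALT))` and
`apri(ast, platelet) = (AST / ULN) / platelet * 100`. The AST upper limit
of normal is configurable and defaults to 40 U/L; the source study does not
print its ULN.

# The combined model

The candidate features are the CNN probability, age, and the eight serum
analytes — the ten variables named by the source as selected; the full
pre-screening candidate list is supplementary-only and unavailable, so the
ten are treated as the candidate set.

1. **VIF screening** (`compute_vif`, `resolve_collinearity`):
   VIF_j = 1/(1 - R^2_j) from the least-squares regression of feature j on
   the others. While any VIF exceeds 5, flagged features are grouped by
   connected components of pairwise |r| >= 0.7 (VIF alone does not identify
   groups; the rule is recorded in the report), and each group keeps the
   feature with the largest *standardized* univariable logistic |beta|
   (z-scored so |beta| is unit-free and comparable across analytes). The
   procedure is idempotent and logs every action. On clean designs it is a
   pass-through — the source found no multicollinearity in its own data.
2. **Select-From-Model** (`select_features_gini`): a random forest is
   fitted and features with Gini importance (normalized mean decrease
   impurity) above the mean importance are retained — the conventional
   default threshold of the named algorithm; the source states none.
3. **Forest fit** (`fit_combined`): stratified fivefold CV; per outer fold
   a grid search (default trees {100, 300, 500} x depth {3, 5, unlimited} x
   min leaf {1, 5}; the source's grid is unpublished) by inner 3-fold AUC,
   fit on the fold-training cases, out-of-fold probability for the held-out
   cases; new-case prediction averages the five forests; the operating
   cutoff is the Youden cutoff on pooled out-of-fold probabilities.

The forest matches scikit-learn conventions (bootstrap, mtry = sqrt(p),
probability prediction as mean leaf class fraction, per-tree-normalized
importances averaged over trees) because the named selection algorithm is
defined in that ecosystem.

# Evaluation statistics

* **AUC**: Mann-Whitney estimator with ties counted 1/2; variance and
  paired comparisons by DeLong structural components; subgroup contrasts by
  the unpaired variant. CIs are normal-approximation, clipped to [0, 1].
* **Cutoffs**: Youden J = sensitivity + specificity - 1 maximized over
  observed scores with "positive iff score >= t"; ties break toward the
  higher (more specific) threshold. The >= convention is safe because the
  published cutoffs are 5-decimal values of continuous scores where the
  boundary case does not occur.
* **Proportion CIs**: exact Clopper-Pearson. The source does not name its
  CI method; exact intervals are conservative and reproducible, and
  published interval endpoints may differ by a point or two. Percent
  display rounds half-up to integers, matching the published table — the
  suite reproduces all thirty combined/FIB-4 metric cells from the printed
  confusion counts exactly.
* **McNemar**: restricted to the metric's case subset; exact two-sided
  binomial when discordant b + c < 25, else chi-square with continuity
  correction (standard practice; the variant is unstated in the source).
* **Kosinski weighted generalized score test** for paired PPV/NPV: each
  subject contributes an observation to procedure j's predictive value when
  j calls it positive (negative for NPV). Under H0 the common value is the
  call-count-weighted pooled estimate p0, and the statistic is
  (p_A - p_B)^2 / V0 with the clustered sandwich variance
  V0 = sum_i [g_iA (d_i - p0)/n_A - g_iB (d_i - p0)/n_B]^2, chi-square on
  1 df. The suite validates it against a 20,000-rep permutation oracle.
* **Calibration**: equal-frequency bins (degenerate score sets collapse to
  their distinct values). **Decision curves**: net benefit
  TP/n - FP/n * pt/(1 - pt) against treat-all and treat-none.

# Known limitations

* The phantom is geometric, not physical; its effect sizes are generator
  knobs. Passing tests validate mechanics and statistics, not clinical
  performance.
* The parity profile (512 px, 500 epochs, augmentation) is provided but not
  exercised under test budgets; the desk profile (64 px) is the tested
  configuration.
* The CNN engine is single-threaded float32; multi-GPU or pretrained-weight
  transfer is out of scope, as are learned registration/segmentation,
  DICOM ingestion, and Child-Pugh/MELD/ALBI scoring.
* Biomarkers are class-conditionally independent; real panels are
  correlated, so the VIF path sees its designed fixtures rather than
  realistic collinearity.
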