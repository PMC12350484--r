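---
title: "Estimating ablation tumor coverage from single CT slices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating ablation tumor coverage from single CT slices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

After percutaneous thermal ablation of a liver tumor, the treatment is
judged by how much of the tumor volume ended up inside the devascularized
ablation zone seen on follow-up contrast CT. The gold-standard measurement
— *percent tumor coverage* — requires 3D segmentation of both regions and
elastic registration of the pre- and post-treatment scans:

$$\mathrm{coverage} = 100 \times
  \frac{V(\mathrm{tumor} \cap \mathrm{ablation})}{V(\mathrm{tumor})}.$$

Segmentation and registration are the bottleneck that keeps volumetric
ablation confirmation out of routine workflows. `slicecov` implements and
stress-tests the alternative: estimate coverage from a *single axial slice*
taken at the isocenter of each region. The premise is geometric — when
coverage is good, the two isocenters lie on nearly the same axial plane, so
the two slices share out-of-plane landmarks (ribs, the diaphragm edge,
liver texture) and their deep-feature representations nearly cancel under
element-wise subtraction. Poor coverage means different planes, different
landmarks, and a large feature difference.

The pipeline is: ground-truth coverage from registered 3D masks → isocenter
slice extraction and standardization → noise-augmented image-pair cohorts →
feature differencing through a convolutional backbone → random-forest /
neural-network prediction heads → ROC and error reporting. A synthetic
phantom generator stands in for patient data, which cannot be
redistributed.

## Ground truth from 3D masks

`percent_tumor_coverage()` counts voxels on two binary masks sharing one
grid (`label_volume` objects carry the mask, mm spacing, and origin; the
third axis is axial, indices are R's native 1-based). Volumes are voxel
count × voxel volume, reported in cm³, and each region is also summarized
as an *equivalent sphere diameter* $d = (6V/\pi)^{1/3}$ — the conventional
single-number size of an irregular region (31.8 cm³ ↦ 3.9 cm; 49.3 cm³ ↦
4.5 cm).

Registration itself is out of scope — the package consumes already
registered masks, as produced by any external elastic-registration tool —
but `registration_quality()` reports the two agreement metrics used to
audit a registration: a windowed structural similarity index (11×11
Gaussian window, standard constants) and the standard error of the
voxelwise intensity differences, $\mathrm{sd}(a-b)/\sqrt{N}$. The latter
definition is a documented choice: "standard error" of a registered pair is
ambiguous, and the intensity-difference reading is the one that needs no
model fit. Note its blind spot, asserted in the tests: a constant intensity
offset has zero-variance differences, hence standard error exactly 0, while
SSIM still penalizes it through its luminance term.

## The phantom generator

`phantom_spec()` / `generate_case()` / `generate_cohort()` produce paired
pseudo-CT volumes with known coverage, emulating the clinical regime the
estimator targets:

* **Grid**: 320×320 voxels in-plane at 1 mm, 40 axial slices at 5 mm —
  the matrix/spacing class of routine multi-detector abdominal CT, so a
  300×300 pixel crop is essentially all anatomy.
* **Lesions**: an ellipsoidal arterially-enhancing tumor (pre volume) and
  an ellipsoidal devascularized ablation zone (post volume). Cohort tumor
  volumes are lognormal with mean 31.8 and sd 27.6 cm³ (clamped to fit the
  grid); ablation volumes are ~1.55× larger, with mild per-axis anisotropy
  so the shapes are not perfect spheres.
* **Background** (shared between pre and post): liver base at 60 pseudo-HU
  plus smoothed Gaussian texture (sd 15, correlation length 6–7.5 mm),
  2–4 rib-like high-intensity arcs whose ring radius drifts linearly with
  the axial position, and a diaphragm-like soft edge whose in-plane
  position also drifts with z. The drift is the point: it makes every
  axial plane visually distinctive, which is the mechanism a slice-based
  estimator exploits. An optional `axial_offset` shifts the background
  between pre and post volumes as a misregistration surrogate.
* **Intensities**: tumor 110, ablation 20, i.i.d. noise sd 10 pseudo-HU.
  Only the contrast ordering matters; everything is windowed downstream.
* **Coverage control**: `generate_cohort()` solves the *axial*
  displacement of the ablation center by 1D bisection until voxel-counted
  coverage hits each requested target (±2 points guaranteed, ±0.25
  typical). Driving coverage through the axial offset means low-coverage
  cases genuinely have their isocenters on different axial planes.
  Unreachable targets (e.g. 100% requested with `shrink < 1`) are flagged
  per case, never dropped silently.
* **Shrinkage**: `shrink` scales the ablation's cranio-caudal semi-axis
  (down to 0.5), emulating late ablation-zone shrinkage along one
  diameter. Off by default so geometric oracles stay exact.

What the phantom does *not* emulate: CT physics (beam hardening, contrast
phases), breathing deformation, irregular lesion shapes, and inter-scanner
protocol variation. Tests passing on phantoms therefore demonstrate that
the pipeline recovers the slice-offset signal it is designed for — not
that the method reaches any particular accuracy on patients.

The per-case coverage distribution of the emulated population is not known
beyond its mean and spread; cohorts default to uniform targets on
[20, 100] (configurable), which exercises all four coverage classes.

**Geometry oracle.** Voxel counting is validated against the closed-form
sphere–sphere intersection (`sphere_intersection_volume()`, the lens /
double-spherical-cap formula). Because the counting error oscillates with
the sub-voxel alignment of sphere and grid, convergence under grid
refinement is asserted on the error averaged over four fixed grid phases,
which falls monotonically (≈0.25% at 2 mm, 0.084% at 1 mm, 0.015% at
0.5 mm); every individual phase stays far below 2% at 1 mm.

## Slice extraction and standardization

The isocenter is the 3D center of mass of the mask, rounded half away from
zero ("center of the ROI" reads as centroid, and the centroid is stable
for concave shapes; the maximal-area slice is available as an option and
coincides with the centroid for symmetric lesions). The axial plane at the
isocenter is window-normalized — default window (−160, 240) pseudo-HU, a
soft-tissue window; the choice is configurable since clinical practice
varies — then cropped/padded to 300×300 pixels about the in-plane ROI
centroid. Padding uses the window minimum (0 after normalization). For
even crop sizes the center pixel convention is left-biased: the requested
center lands on index 151 of 1…300, making the crop idempotent on an
already-standardized image.

## Augmentation cohorts

Training data are *pairs* (tumor slice, ablation slice) labeled with the
case's coverage. Three cohorts of increasing size are built from n cases:

1. originals only (n pairs);
2. plus Gaussian-noised copies, exclusively paired — original/original and
   noise/noise (2n);
3. crossed — all four original/noise combinations per case (4n).

Noise is additive Gaussian with variance 0.001 and non-zero mean (default
0.01; the mean's exact value is a free parameter) on the [0, 1] intensity
scale, clipped back to [0, 1]. One noise realization is drawn per case and
ROI from a sub-seed hashed out of the case id, and reused across the
level-3 pairings, so a case's four combinations share the same noised
images and adding cases never reshuffles existing draws. With 182 cases
the three cohorts hold 182, 364 and 728 pairs; an 80:20 case-level split
(round half up: 146:36) scales to 292:72 and 584:144. Splitting happens on
cases *before* augmentation, so no augmented copy of a case can leak
across the boundary. A 90° rotation augmentation is implemented
(`rotate90()`) but not used by the canonical cohorts, whose sizes admit
only the noise pairings.

## Feature differencing

Each 300×300 slice is bilinearly resized to 224×224, replicated to three
channels, and standardized with the conventional ImageNet channel
statistics — the input contract of VGG-style backbones. Two interchangeable
extractors produce a 25,088-length feature vector:

* `vgg16_extractor()` instantiates the VGG16 convolutional architecture
  (thirteen 3×3 convolutions in five blocks, 2×2 max pooling, flatten at
  7×7×512 = 25,088). Kernels are He-initialized from a fixed seed;
  pretrained ImageNet kernels can be supplied as a file, and asking for a
  missing weights file raises an explicit capability error rather than a
  silent fallback. The forward pass is an im2col + BLAS matrix-multiply
  implementation, exact in shape and receptive field.
* `randconv_extractor()` is the default working backbone: 2×2 average
  pooling to 112×112, then three He-initialized conv/ReLU/max-pool stages
  (3→32→128→128 channels), flattened at 14×14×128 — the same 25,088
  length on a twice-finer spatial grid at a small fraction of the
  compute. The gentle initial pooling is deliberate: the axial signature
  that separates *neighboring* slices is a ~1-pixel shift of the rib
  arcs, which survives 2× pooling but not 4×.

Random-convolution features are a standard trick: they preserve local
image structure without any training, so feature-space distance grows
with slice separation — the only property the predictors need, and one the
tests assert directly on a phantom. Both backbones are deterministic at
inference (no dropout, no batch effects).

The model input is the element-wise difference, tumor minus ablation
(order fixed by convention), computed per pair with per-slice feature
caching so level-3 cohorts featurize each distinct slice once.

## Prediction heads

* **Classification**: coverage is binned into `<=50` (incomplete),
  `50-70` (partially incomplete), `70-90` (acceptable), `>=90` (complete).
  The interior boundary convention — 50 down, 70 up, 90 up — is fixed and
  documented because the bin edges are ambiguous as written; the outer
  bins take their stated values literally. A 100-tree random forest
  (`ranger`, remaining hyperparameters at library defaults, single thread
  + seed for determinism) predicts by tree voting; `predict_class()`
  returns the vote fractions, and ties break toward the lower class — the
  conservative direction for a completeness flag.
* **Regression**: a 100-tree random forest, and a DNN with ReLU hidden
  layers of 4096 and 1024 units, linear output, trained exactly 30 epochs
  with Adam (lr 1e-4, batch size 16) on mean-squared error. Optimizer,
  rate and batch size are recorded choices among standard defaults.
  Inputs and targets are standardized internally (a fixed 30-epoch
  schedule cannot otherwise reach the output scale); predictions return
  on the percent scale. The per-epoch loss is recorded and a
  smoothed-monotone convergence flag stored. Predictions of either
  variant are capped at 100% — a tumor cannot be more than fully covered —
  with no lower clamp.

## Evaluation

`classification_report()` gives accuracy, the 4×4 confusion matrix,
per-class and macro TPR/TNR at the argmax decision, and one-vs-rest ROC
AUCs (scores = vote fractions, trapezoidal integration via pROC; macro =
unweighted mean over evaluable classes, since no averaging rule is
canonical). Classes lacking positives or negatives are skipped with a
warning. The AUC implementation is cross-checked in the tests against an
independent brute-force pair-counting oracle (ties ½), exactly, on small
fixtures.

`regression_report()` gives MSE/RMSE/MAE of the signed error
(predicted − true), Pearson and Spearman correlations of error against
true coverage (is the model compressing toward the mean?), and a
Kolmogorov–Smirnov test of error normality with parameters estimated from
the sample — the customary descriptive check, with the caveat that
estimating the parameters inflates the p-value.

## Orchestration, determinism, problem sizes

`run_pipeline()` composes the stages and persists every intermediate
(CSV manifests, JSON metrics, JSON config audit trail). One global seed
fans out into per-stage, per-case sub-seeds via a fixed string hash, so
results are bit-reproducible per configuration and adding cases does not
reshuffle existing ones; the test suite asserts byte-identical metrics
across reruns. Volumes are rendered one case at a time and reduced to
their two standardized slices immediately, so memory stays flat in n.

The bundled benchmark scale is 150 phantom cases (120:30 split, level-1
cohort, random-convolution backbone) — large enough for all four coverage
classes to be populated and for a 20-permutation label test, small enough
to run on a laptop core in a few minutes. At that scale, the forest
regressor reaches a held-out MAE around 10–14 percentage points (beating
every label-permuted refit, whose MAEs sit at 23–26), and the classifier's
macro one-vs-rest AUC sits around 0.73–0.88 depending on the seed — the
test-set side has only 30 cases, so per-class AUCs are noisy; the error
also compresses toward the mean (negative error–truth correlation),
over-predicting low coverage and under-predicting high.

## Known limitations

* The phantom's coverage signal travels through one channel (axial offset
  of background landmarks); real anatomy offers both more confounders and
  more cues, in unknown proportion.
* Elongated or concave lesions violate the single-slice premise in the
  cranio-caudal direction by construction; nothing in a 2D axial slice can
  see them.
* The DNN head at the full 25,088-input width is memory-hungry (~0.8 GB of
  weights alone) and, consistent with its fixed 30-epoch budget, weaker
  than the forest; it exists for completeness and runs in tests at reduced
  width.
* `registration_quality()` audits a registration; it cannot substitute for
  one. Misregistered masks bias coverage in ways no downstream step can
  detect.
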