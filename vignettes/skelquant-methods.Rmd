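---
title: "Quantifying skeletal tumor burden in small-animal PET/CT: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying skeletal tumor burden in small-animal PET/CT: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(skelquant)
```

## The problem

Longitudinal PET/CT imaging of bone-marrow-involved cancers in mice — for
example disseminated multiple myeloma models — has to contend with three
obstacles that ordinary whole-ROI quantification does not handle:

1. **Excretion artifacts.** The radiotracer accumulates in urine and feces.
   The bladder and rectum sit directly against the pelvis, and the apparent
   signal spills into pelvic bone, inflating SUV metrics by large,
   scan-to-scan-variable amounts.
2. **Repositioning.** The animal lies differently at every imaging session.
   Non-rigid registration can force voxels into alignment, but there is no
   way to verify it preserved the true relative positions of the signal, so
   this package deliberately avoids it.
3. **Diffuse lesions.** Marrow lesions often lack crisp PET boundaries, so
   threshold-based tumor segmentation is not reproducible; quantification is
   anchored to CT-derived skeletal anatomy instead.

`skelquant` operates on five fixed skeletal ROIs — spine, right femoral
body, left femoral body, pelvis & pelvic joints (PPJ), sacrum — encoded as
labels 1–5 (see `roiLabels()`). The labels are disjoint; sacrum can be
pooled with spine or PPJ (`combineROIs()`), and those pooled rows are
reported alongside the singles.

All geometry is computed in world millimetres through each volume's affine,
never in index units, so anisotropic or rotated grids are handled uniformly.
Quantification runs on the CT grid (masks are CT-derived); PET is resampled
onto it with trilinear interpolation when grids differ. Body-weight SUV with
unit tissue density is assumed; decay correction is the caller's
responsibility via the `decay_interval` argument of `computeSUV()`.

## Spillover removal

The algorithm mirrors the three-step structure visible in excretion-artifact
masking:

1. **Background statistics.** Mean and sample standard deviation of SUV over
   all voxels outside the ROI union dilated by `pad_voxels` (default 2; the
   dilation keeps bone-adjacent partial-volume voxels out of the
   statistics). The threshold is `mean + k_sigma * std` with `k_sigma = 3`,
   the conventional outlier cut — only "a standard-deviation-based
   threshold" is prescribed by the method, so the multiplier is exposed as a
   parameter. Note that the statistics intentionally include the hotspot
   itself; with a bladder at peak SUV ≈ 30 this inflates the std and adapts
   the threshold to the artifact magnitude.
2. **Extreme regions.** 26-connected components of supra-threshold non-ROI
   voxels with at least `min_region_voxels = 10` members (suppressing
   isolated noise voxels, which would otherwise appear at the ~0.1% rate
   expected from Gaussian noise). Each region carries its unweighted
   geometric center and peak SUV.
3. **Gradient-guided growth.** From each region's own voxels, a
   frontier-synchronous breadth-first growth over 26-neighbors adds a voxel
   iff (a) its smoothed SUV gradient has positive dot product with the
   vector toward the region center, (b) it lies within `max_growth_mm = 3`
   of the region boundary (exact separable Euclidean distance transform),
   and (c) it is unclaimed by a higher-peak region. Spillover decays with
   distance from its source, so its gradient points *toward* the source:
   that is the direction criterion. Growth is allowed to enter skeletal
   ROIs — that is precisely the contamination being removed — while region
   *detection* is restricted to non-ROI voxels.

Design choices worth stating: the growth criterion is the *sign* of the dot
product (no angular threshold — one fewer knob); gradients are estimated
after Gaussian smoothing at one voxel spacing because raw finite differences
on PET noise are directionally unstable; the frontier-synchronous BFS makes
the mask independent of traversal order, and ties between regions are broken
by descending peak SUV then lexicographic center, so results are fully
deterministic.

The phantom generator decomposes noiseless PET into background + lesion +
spillover per voxel, which gives the algorithm a per-voxel referee: on the
default pelvic phantom the mask captures ≥ 80% of voxels whose spillover
share exceeds 25% while touching ≤ 5% of pelvic voxels whose share is below
5%, and on zero-excretion phantoms the whole stage is an exact no-op.

## Long-axis projection

Assuming bone shape is stable over time, the first principal component of a
bone's voxel coordinates (unweighted, world mm) estimates its longitudinal
axis. Voxels are projected onto it (`t = (x - centroid) · direction`) and
binned into `n_bins = 40` equal-width slices; per-slice metric panels then
localize SUV/HU changes along the bone. Choices:

* **40 bins** resolves joint-adjacent features at femur scale (~0.2 mm bins
  on a ~8 mm femur) without starving bins; bin count/width is configurable
  because neither is canonical.
* **Sign convention.** PCA directions are sign-ambiguous; `orientAxis()`
  flips toward a reference axis (the subject's baseline) or, absent one,
  makes the largest world component positive. Cross-timepoint profiles are
  meaningless without this.
* **Normalization.** Per-scan bins span `[min t, max t]` and positions are
  reported normalized to [0, 1] for cross-subject plots; *fixed-edges*
  binning (edges carried over from the subject's baseline) is used for
  within-subject deltas and segment selection, so a segment like the
  acetabular `[0.7, 1]` range selects the same anatomy at every timepoint.
* **Empty bins** are reported as missing, never zero-filled.
* **The spine is excluded** from projection (a curved, posture-dependent
  structure has no meaningful straight axis); `projectROI()` refuses it
  unless explicitly overridden, and then warns.

## Metric panel

`suvPanel()`: mean, median, q75/q90/q95 (linear interpolation of order
statistics — the common default, stated nowhere, so pinned here), max,
sample std (ddof = 1; 0 for n = 1), and the fraction of voxels strictly
above the SUV threshold (default 2.5). `huPanel()`: mean, max, std, the
trabecular band fraction 300 < HU < 800 and cortical fraction HU > 1000,
both strict, following the printed inequality notation. Fractions are exact
rational counts.

## Longitudinal statistics

Every subject is its own control: deltas are `value − baseline_value`
against the subject's day-0 scan (absolute differences, not ratios). Sex
comparisons are two-sided Welch t-tests per (day, ROI, metric) — the
unequal-variance form is the safer default when only "t-tests" is
specified; the pooled Student form sits behind `var_equal = TRUE`. Raw
p-values are reported; Benjamini–Hochberg adjustment is available but off
by default, matching the convention of presenting unadjusted grids.
Degenerate cells (both groups constant and equal) report t = 0, p = 1
rather than NaN.

`segmentTTest()` composes the machinery: baseline axis and bin edges per
subject, fixed-edges slicing at follow-up, segment aggregation, deltas, and
the sex test — the acetabular segment of the PPJ (normalized `[0.7, 1]`)
being the configured default.

## Segmentation

A compact attention U-Net classifies 2D sagittal CT slices into the six
labels. Skip connections pass through additive attention gates (the coarser
decoder feature gates the encoder skip via a 1×1-conv bottleneck and
sigmoid); a fixed sinusoidal positional encoding of the slice index is
broadcast and concatenated to the final decoder feature map, followed by one
extra convolution to class scores. The encoding is the mechanism that lets
a 2D model tell visually identical left and right femur slices apart; the
package demonstrates this property directly on mirror-symmetric femur
phantoms, where the same training budget with the encoding achieves strictly
higher left/right femur Dice than without it.

The implementation is a self-contained R layer kit (im2col convolutions,
max-pooling with deterministic tie-breaking, nearest upsampling, softmax
cross-entropy and soft-Dice losses, Adam), with analytic gradients verified
against numerical differentiation in the test suite. Defaults are
desk-scale: tests train 2-level, 8-channel models on ~50 phantom slices in
tens of seconds of CPU. Architecture depth/width, encoding length and loss
are configuration (`segConfig()`), since the exact training-scale
hyperparameters of a production model are a deployment concern, not part of
the method. Evaluation (`evaluateMasks()`) reports per-ROI and pooled Dice,
mIoU, recall and precision on the 3D assembled masks; labels absent from
both maps are *missing*, not 0 or 1, and the identity
`Dice = 2·IoU/(1 + IoU)` is asserted property-style.

## The digital mouse phantom

`phantomSpec()` defines the reference phantom: a 19.2 × 32 × 19.2 mm field
of view at 0.2 mm isotropic spacing containing a curved spinal tube, sacral
cylinder, two elongated iliac-blade ellipsoids with acetabular spheres
(together the PPJ), and two femurs (head sphere + shaft cylinder), all
painted from signed-distance functions with a 0.25 mm cortical shell (1200
HU) around trabecular cores (500 HU) in a soft-tissue body (40 HU) in air
(−1000 HU); CT noise 30 HU. The pelvis proportions deliberately make its
first principal component cranio-caudal, with the acetabula at ~0.8–1.0 of
the normalized axis. PET is background SUV 0.3 (noise 0.05) plus three
joint-adjacent lesion Gaussians (σ 0.28 mm; right femoral head, left
acetabulum, sacroiliac) whose peak follows the day schedule 0/1.5/4/5/6 SUV
at days 0/11/18/25/32, plus a bladder hotspot (peak SUV 30, Gaussian decay
1.5 mm) anterior-caudal of the pelvis. HU levels sit inside the reported
trabecular (300–800) and cortical (>1000) bands; none of these values claim
to be acquisition constants — they are chosen once as plausible preclinical
magnitudes.

Two generator details are consequences of validation needs, not
physiology:

* Lesion centers sit ≥ 3.3σ inside the bone surface so that on
  zero-excretion phantoms no lesion tail crosses the detection threshold
  outside the skeleton — which is what makes the "spillover removal is an
  exact no-op on clean data" property testable at all.
* **Repositioning is a rigid change of the world affine** with the voxel
  lattice fixed to the anatomy: the same lattice, re-expressed in a moved
  scanner frame. This models the positioning problem the projection method
  solves (axes and bins must be recovered in world space) while keeping
  per-bone voxel sets identical, which is what a ±1-voxel-per-bin
  cross-scan consistency check presumes. What it does *not* model is
  re-voxelization noise — a real repositioned scan re-samples the anatomy
  and flips boundary voxels. That effect is exercised separately by
  resampling transformed label maps through `resampleToGrid()` (nearest
  neighbor), where per-bone counts stay within 1% at the default grid and
  the femur axis is still recovered within 2°.

Sex effects are parameter shifts with known ground truth: females get a
1.6× lesion-amplitude multiplier at day 18 and a 180 HU acetabular
decrement at days 25/32. Between-subject variability is a log-normal
lesion-amplitude factor (σ = 0.15) and a constant per-subject HU offset
(σ = 10 HU). Everything is seeded and bitwise-reproducible.

What passing tests on this phantom do **not** show: robustness to scanner
point-spread, attenuation or scatter, Poisson count noise, soft-tissue
heterogeneity, genuinely deforming anatomy, or segmentation at realistic
anatomical complexity. The phantom validates the *logic* of each stage
against exact ground truth, not clinical performance.

## Problem sizes used by the validation suite

Simulation studies state their sizes as package choices: the type-I
calibration runs 200 independent zero-effect cohorts (4 females + 4 males)
and the power checks 30 effect cohorts per cell, all on the half-resolution
(0.4 mm) phantom — the statistical properties under test are
resolution-independent, and ~3,000 sessions at 0.4 mm are a desktop-scale
computation. Geometry-sensitive checks (spillover recovery, axis recovery,
bin-count consistency, lesion localization) run at the default 0.2 mm.
Desk-scale segmentation checks use 2-level, 8-channel models; the mirrored
femur comparison trains both arms for 40 epochs with identical seeds.

## Numerical choices and degenerate inputs

* Distance caps in the spillover growth use an exact separable squared
  Euclidean distance transform; exactness holds for orthogonal affines
  (rigid rotation × spacing), which covers every grid the package produces.
* PCA on a near-isotropic voxel cloud (first-vs-second eigenvalue gap below
  5% of total variance) is flagged `stable = FALSE`; a single-point or
  empty mask errors.
* `resampleToGrid()` fills out-of-grid voxels with 0 (SUV) or −1024 (HU)
  and clamps interpolated SUV at 0.
* Max-pooling ties break deterministically (top-left wins); BFS order never
  affects results; all stochastic stages consume explicit seeds, and
  derived seeds stay within 32-bit integer range.
* CSV reports format floats with fixed `%.6g` so identical runs produce
  byte-identical files.

## Known limitations

Straight-axis projection is restricted to straight bones — the spine needs
a curved parameterization that is out of scope. The phantom's affine-based
repositioning understates boundary-voxel churn (see above). The
segmentation module is desk-scale by design; reproducing production-grade
Dice on real scans would require real training data and GPU-scale budgets,
neither of which this package claims. No partial-volume correction or
scatter modeling is attempted; the spillover mask excludes contaminated
voxels rather than recovering their true values.
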