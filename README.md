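# skelquant

Semi-automated quantification of bone-involved tumor burden in longitudinal
small-animal PET/CT.

Preclinical imaging of marrow-involved cancers (e.g. disseminated multiple
myeloma in mice) runs into three practical problems: radiotracer excreted in
urine and feces creates intense artifacts right next to the pelvis; animals
lie differently at every session, and non-rigid registration cannot be
trusted to preserve the true relative positions of signal; and diffuse
marrow lesions lack PET boundaries, so tumor-threshold segmentation is not
reproducible. `skelquant` implements a pipeline for this setting, built
around five CT-defined skeletal ROIs (spine, right/left femoral body,
pelvis & pelvic joints, sacrum):

* **Spillover removal.** Extreme-SUV regions outside the skeleton are found
  with a background threshold *mean + k·std* (k = 3), and an exclusion mask
  is grown over 26-neighbors whose SUV gradient points toward the region
  center — spillover decays with distance from its source, so its gradient
  points back at it — capped at 3 mm from the region boundary.
* **Long-axis projection.** Each straight bone's longitudinal direction is
  the first principal component of its voxel coordinates in world mm;
  voxels are sliced perpendicular to it into 40 bins, giving
  location-resolved SUV/HU profiles comparable across scans without any
  non-rigid registration. The curved spine is excluded by design.
* **Metric panel.** SUV mean / median / q75 / q90 / q95 / max / std and the
  fraction of voxels with SUV > 2.5; HU mean / max / std with the
  trabecular (300 < HU < 800) and cortical (HU > 1000) band fractions.
* **Longitudinal statistics.** Each subject is its own control: metric
  deltas against the subject's day-0 baseline, compared female-vs-male with
  two-sided Welch t-tests per (day, ROI, metric), whole-bone or restricted
  to an axial segment such as the acetabular range of the pelvis.
* **Segmentation (desk scale).** A compact attention U-Net over 2D sagittal
  CT slices with a fixed sinusoidal positional encoding of the slice index
  concatenated before the final convolution — the encoding is what lets a
  2D model distinguish visually identical left and right femur slices — and
  3D Dice / mIoU / recall / precision evaluation.
* **Digital mouse phantom.** A fully synthetic PET/CT generator (skeleton
  painted from signed-distance functions, joint-adjacent lesions growing
  over imaging days, a bladder hotspot with a Gaussian spillover tail,
  sex-dependent late acetabular bone loss, rigid repositioning, seeded
  noise) that returns the exact per-voxel SUV decomposition, so every
  pipeline stage is validated against ground truth.

## Worked example

Generate a phantom session at day 18, remove excretion spillover, and
profile the pelvis along its long axis:

```r
library(skelquant)

spec <- phantomSpec(sex = "male", seed = 1)        # 0.2 mm digital mouse
ses  <- generateSession(spec, day = 18L)

spill <- spilloverMask(ses$pet, ses$labels)
spill
#> SpilloverMask: 113346 voxels excluded, 1 source region(s)
#>   spine      0.00% removed
#>   femur_r    13.12% removed
#>   femur_l    21.06% removed
#>   ppj        36.28% removed
#>   sacrum     61.02% removed

session <- asScanSession(ses, "M1", "male", 18L)
prof <- projectROI(session, "ppj", n_bins = 40L, spill = spill)
head(profileMetrics(prof)[, c("bin_index", "t_center_norm", "voxel_count",
                              "suv_mean", "suv_max", "hu_mean")], 3)
#>   bin_index t_center_norm voxel_count  suv_mean   suv_max  hu_mean
#> 1         1        0.0125          44 0.2975620 0.4365304 1197.737
#> 2         2        0.0375          48 0.3208113 0.4251515 1202.025
#> 3         3        0.0625          84 0.2956689 0.4700340 1204.065
```

One extreme region (the simulated bladder, peak SUV ≈ 30) was detected.
Its grown mask removes about a third of the pelvis-and-pelvic-joints ROI
and over half of the adjacent sacrum — the voxels whose ground-truth
spillover share is high — plus a fringe of the femoral heads, which sit
right at the 3 mm growth boundary where weak residual spillover gradients
still point back at the bladder. The surviving profile bins report
uncontaminated SUV around the 0.3 background, and the bin with maximal
SUV mean lands at normalized position 0.91, at the generated acetabular
lesion.

Whole-cohort runs go through `generateCohort()` → `runPipeline()`, which
writes per-session spillover reports, profiles, metric panels, the
baseline-delta table, per-day female-vs-male p-value grids and segment
tests into a report directory. A thin command-line front end with
`simulate / despill / project / quantify / segment / run` subcommands is
installed at `inst/cli/skelquant.R`.

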