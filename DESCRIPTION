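Package: skelquant
Title: Quantification of Skeletal Tumor Burden in Small-Animal PET/CT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Semi-automated quantification of bone-involved tumor burden in
    longitudinal small-animal PET/CT. Provides NIfTI volume handling on
    co-registered PET (SUV) and CT (HU) grids with multi-label skeletal
    regions of interest; a gradient-based algorithm that detects extreme-SUV
    excretion hotspots (bladder, feces) outside the skeleton and grows an
    exclusion mask over spillover-contaminated voxels; PCA long-axis fitting
    and perpendicular slicing of individual bones for location-resolved SUV
    and HU profiles; whole-region metric panels (SUV mean/median/quantiles/
    max/std, fraction above threshold, trabecular and cortical HU bands);
    baseline-delta longitudinal statistics with female-versus-male Welch
    t-tests; a compact slice-wise attention U-Net with sinusoidal positional
    encoding for multi-label bone segmentation and 3D overlap evaluation;
    and a fully synthetic digital-mouse phantom generator with per-voxel
    ground truth for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    RNifti,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
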