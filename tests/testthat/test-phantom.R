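# Phantom generator ground truth and determinism.

test_that("a fully quiet phantom is pure background", {
  spec <- smallSpec(seed = 9, lesions = NULL, bladder = cleanBladder(),
                    hu_noise_sd = 0, suv_noise_sd = 0,
                    subject_sd = list(lesion_amp = 0, hu_offset = 0))
  ses <- generateSession(spec, 18L)
  expect_equal(unique(as.vector(imgData(ses$pet))), spec$suv_background)
  expect_true(all(ses$truth$spill == 0))
  expect_true(all(ses$truth$lesion == 0))
})

test_that("lesion peaks follow the day schedule", {
  # lesion centered exactly on a voxel center of the 0.4 mm grid (voxel
  # centers sit at odd multiples of 0.2 mm), inside the femoral head
  les <- data.frame(name = "head", bone = "femur_r",
                    x = 5.0, y = 3.8, z = 0.2, sigma = 0.28)
  spec <- smallSpec(seed = 9, bladder = cleanBladder(), lesions = les,
                    hu_noise_sd = 0, suv_noise_sd = 0,
                    subject_sd = list(lesion_amp = 0, hu_offset = 0))
  ses <- generateSession(spec, 18L)
  femur <- combineROIs(ses$labels, "femur_r")
  # peak voxel inside the lesion's bone = background + scheduled amplitude
  expect_equal(max(imgData(ses$pet)[femur]), 0.3 + 4.0, tolerance = 1e-6)
  ses25 <- generateSession(spec, 25L)
  expect_equal(max(imgData(ses25$pet)[femur]), 0.3 + 5.0, tolerance = 1e-6)
  expect_error(generateSession(spec, 13L), "not in the phantom schedule")
})

test_that("SUV decomposition components sum to the noiseless total", {
  ses <- smallSession(18L)
  tot <- ses$truth$background + ses$truth$lesion + ses$truth$spill
  expect_equal(tot, ses$truth$total_noiseless, tolerance = 1e-12)
  expect_true(all(ses$truth$lesion >= 0) && all(ses$truth$spill >= 0))
})

test_that("femur voxel count matches an independent fine-grid volume oracle", {
  ses <- smallSession(0L)
  n <- sum(combineROIs(ses$labels, "femur_r"))
  # membership test re-implemented from the documented solid: head sphere
  # r=1.1 at (5.0,4.05,0.3) plus shaft cylinder r=0.9, length 6.5 along u
  u <- c(0.2208, 0.9735, 0.0602); u <- u / sqrt(sum(u^2))
  h <- c(5.0, 4.05, 0.3)
  fine <- 0.1
  gx <- seq(2.5, 9.5, by = fine)
  gy <- seq(1.5, 12.5, by = fine)
  gz <- seq(-2, 3, by = fine)
  G <- as.matrix(expand.grid(x = gx, y = gy, z = gz))
  W <- sweep(G, 2, h)
  t <- W %*% u
  inSphere <- rowSums(W^2) <= 1.1^2
  rad2 <- rowSums(W^2) - t^2
  inCyl <- t >= 0 & t <= 6.5 & rad2 <= 0.9^2
  vol <- sum(inSphere | inCyl) * fine^3
  expect_lt(abs(n * 0.4^3 - vol) / vol, 0.05)
})

test_that("identical spec and day reproduce bitwise-identical sessions", {
  spec <- smallSpec(seed = 12)
  an <- smallAnatomy()
  s1 <- generateSession(spec, 18L, an)
  s2 <- generateSession(spec, 18L, an)
  expect_identical(imgData(s1$pet), imgData(s2$pet))
  expect_identical(imgData(s1$ct), imgData(s2$ct))
  expect_identical(s1$pet@transform, s2$pet@transform)
})

test_that("cohort generation writes the declared files and manifest", {
  out <- file.path(tempdir(), "cohort_test")
  unlink(out, recursive = TRUE)
  specs <- cohortSpecs(1, 1, seed = 3, spacing = 0.4)
  man <- generateCohort(specs, c(0L, 11L, 18L), out)
  expect_equal(nrow(man), 6L)
  expect_length(list.files(out, pattern = "nii.gz$"), 18L)
  expect_true(file.exists(file.path(out, "manifest.csv")))
  expect_true(file.exists(file.path(out, "truth.json")))
  # deterministic regeneration
  out2 <- file.path(tempdir(), "cohort_test2")
  unlink(out2, recursive = TRUE)
  generateCohort(cohortSpecs(1, 1, seed = 3, spacing = 0.4),
                 c(0L, 11L, 18L), out2)
  f1 <- readVolume(file.path(out, "F1_day18_pet.nii.gz"), "SUV")
  f2 <- readVolume(file.path(out2, "F1_day18_pet.nii.gz"), "SUV")
  expect_identical(imgData(f1), imgData(f2))
  # manifest rows load into valid sessions
  ses <- loadSession(readManifest(file.path(out, "manifest.csv"))[1, ])
  expect_s4_class(ses, "ScanSession")
})

test_that("with sex effects disabled, parameters are sex-blind", {
  eff0 <- list(suv_mult_day18 = 1, hu_drop = 0, hu_drop_days = integer())
  sf <- phantomSpec(sex = "female", seed = 4, spacing = 0.4,
                    sex_effects = eff0)
  sm <- phantomSpec(sex = "male", seed = 4, spacing = 0.4,
                    sex_effects = eff0)
  expect_identical(sf[setdiff(names(sf), "sex")],
                   sm[setdiff(names(sm), "sex")])
  # and realized volumes differ only through the identical noise stream
  s1 <- generateSession(sf, 18L)
  s2 <- generateSession(sm, 18L)
  expect_identical(imgData(s1$pet), imgData(s2$pet))
})

test_that("spillover truth masks are nested in dominance and localized", {
  ses <- smallSession(18L)
  m40 <- spilloverTruthMask(ses$truth, 0.40)
  m25 <- spilloverTruthMask(ses$truth, 0.25)
  expect_true(all(which(m40) %in% which(m25)))
  expect_gt(sum(m25), 0)
  # all dominated voxels lie near the bladder center
  idx <- which(m25)
  xyz <- skelquant:::.voxelWorldCoords(arrayInd(idx, dim(m25)),
                                       ses$pet@transform)
  bl <- ses$truth$rigid %*% c(0, 4.6, 3.4, 1)
  dist <- sqrt(rowSums(sweep(xyz, 2, bl[1:3])^2))
  expect_lt(max(dist), 6)
  # zero-excretion phantom -> empty at any dominance
  clean <- generateSession(smallSpec(seed = 9, bladder = cleanBladder()), 18L)
  expect_false(any(spilloverTruthMask(clean$truth, 0.1)))
})

test_that("rigid repositioning preserves nearest-neighbour label counts within 1%", {
  # at the default 0.2 mm resolution: boundary-voxel churn scales with
  # spacing, and the 1% tolerance is a property of the reference grid
  spec <- phantomSpec(sex = "male", seed = 9, spacing = 0.2)
  an <- buildAnatomy(spec)
  base <- generateSession(spec, 0L, an)
  ref <- ImageVolume(array(0, dim(imgData(base$ct))),
                     transform = base$labels@transform, modality = "HU")
  n0 <- vapply(names(roiLabels())[-1],
               function(r) sum(combineROIs(base$labels, r)), 0L)
  for (day in c(11L, 25L)) {
    ses <- generateSession(spec, day, an)
    labR <- resampleToGrid(ses$labels, ref)
    n1 <- vapply(names(roiLabels())[-1],
                 function(r) sum(combineROIs(labR, r)), 0L)
    expect_true(all(abs(n1 - n0) / n0 <= 0.01))
  }
})
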