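# Domain types, NIfTI I/O, resampling, SUV conversion, ROI combination.

test_that("NIfTI round-trip preserves data, spacing and affine", {
  set.seed(1)
  d <- array(runif(4 * 4 * 4), c(4, 4, 4))
  v <- ImageVolume(d, spacing = c(0.2, 0.2, 0.2), modality = "SUV")
  f <- tempfile(fileext = ".nii.gz")
  writeVolume(v, f)
  v2 <- readVolume(f, "SUV")
  expect_equal(imgData(v2), d, tolerance = 1e-7)  # float32 storage
  expect_equal(voxelSpacing(v2), c(0.2, 0.2, 0.2), tolerance = 1e-6)
  expect_lt(max(abs(worldTransform(v2) - worldTransform(v))), 1e-5)

  # a rotated, anisotropic affine survives the sform round-trip
  th <- 0.4
  R <- diag(3)
  R[1:2, 1:2] <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  A <- diag(4)
  A[1:3, 1:3] <- R %*% diag(c(0.2, 0.3, 0.5))
  A[1:3, 4] <- c(-3, 2, 1)
  v3 <- ImageVolume(array(rnorm(60)^2, c(3, 4, 5)), transform = A,
                    modality = "SUV")
  f3 <- tempfile(fileext = ".nii.gz")
  writeVolume(v3, f3)
  v4 <- readVolume(f3, "SUV")
  expect_lt(max(abs(worldTransform(v4) - A)), 1e-5)
})

test_that("readVolume rejects non-3D images and missing files", {
  f <- tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(RNifti::asNifti(matrix(0, 4, 4)), f)
  expect_error(readVolume(f, "SUV"), "3D")
  expect_error(readVolume(tempfile(), "SUV"), "not found")
  expect_error(writeVolume(ImageVolume(array(0, c(2, 2, 2))), tempdir()),
               "directory")
})

test_that("label maps round-trip as uint8 and reject foreign ids", {
  lm <- LabelMap(array(sample(0:5, 64, TRUE), c(4, 4, 4)),
                 spacing = c(0.2, 0.2, 0.2))
  f <- tempfile(fileext = ".nii.gz")
  writeLabelMap(lm, f)
  lm2 <- readLabelMap(f)
  expect_identical(imgData(lm2), imgData(lm))
  expect_error(LabelMap(array(7L, c(2, 2, 2))), "unknown label")
})

test_that("volume validity constraints are enforced", {
  expect_error(ImageVolume(array(-1, c(2, 2, 2)), modality = "SUV"),
               ">= 0")
  expect_error(ImageVolume(array(-2000, c(2, 2, 2)), modality = "HU"),
               "-1024")
  expect_error(new("ImageVolume", data = array(0, c(2, 2, 2)),
                   spacing = c(1, 1, 1), transform = matrix(0, 4, 4),
                   modality = "SUV"), "invertible")
})

test_that("resampling onto the native grid is the identity", {
  set.seed(2)
  v <- ImageVolume(array(runif(5 * 6 * 7), c(5, 6, 7)),
                   spacing = c(0.3, 0.3, 0.3), modality = "SUV")
  r <- resampleToGrid(v, v, "trilinear")
  expect_equal(imgData(r), imgData(v), tolerance = 1e-12)
  rn <- resampleToGrid(v, v, "nearest")
  expect_identical(imgData(rn), imgData(v))
})

test_that("constant volumes stay constant in the interior after resampling", {
  v <- ImageVolume(array(2.5, c(8, 8, 8)), spacing = c(0.25, 0.25, 0.25),
                   modality = "SUV")
  A <- worldTransform(v)
  A[1:3, 4] <- A[1:3, 4] + c(0.1, -0.07, 0.12)
  ref <- ImageVolume(array(0, c(8, 8, 8)), transform = A, modality = "SUV")
  r <- resampleToGrid(v, ref, "trilinear")
  expect_equal(unique(as.vector(imgData(r)[2:7, 2:7, 2:7])), 2.5)
})

test_that("a one-voxel world shift resamples to a one-index shift (nearest)", {
  set.seed(3)
  d <- array(runif(6 * 6 * 6), c(6, 6, 6))
  v <- ImageVolume(d, spacing = c(0.2, 0.2, 0.2), modality = "SUV")
  A <- worldTransform(v)
  A[1, 4] <- A[1, 4] + 0.2  # shift origin by exactly one voxel along x
  ref <- ImageVolume(array(0, c(6, 6, 6)), transform = A, modality = "SUV")
  r <- resampleToGrid(v, ref, "nearest")
  # reference voxel i sits where source voxel i+1 was
  expect_identical(imgData(r)[1:5, , ], d[2:6, , ])
  expect_true(all(imgData(r)[6, , ] == 0))  # out-of-grid fill for SUV
})

test_that("SUV conversion matches the body-weight formula", {
  act <- ImageVolume(array(500, c(3, 3, 3)), modality = "ACTIVITY")
  s <- computeSUV(act, injected_dose = 500, body_weight = 1,
                  decay_interval = 0, half_life = 100)
  expect_equal(unique(as.vector(imgData(s))), 1.0)
  s2 <- computeSUV(act, 500, 1, decay_interval = 100, half_life = 100)
  expect_equal(unique(as.vector(imgData(s2))), 2.0)  # one half-life
  set.seed(4)
  a <- array(runif(64, 10, 100), c(4, 4, 4))
  dose <- 3.7e6; wt <- 22; dt <- 1800; hl <- 45720
  s3 <- computeSUV(ImageVolume(a, modality = "ACTIVITY"), dose, wt, dt, hl)
  expect_equal(imgData(s3), a / (dose * 2^(-dt / hl) / wt),
               tolerance = 1e-12)
  expect_error(computeSUV(act, 0, 20), "> 0")
  expect_error(computeSUV(act, 100, -1), "> 0")
})

test_that("ROI combination is additive over disjoint labels", {
  set.seed(5)
  lm <- LabelMap(array(sample(0:5, 1000, TRUE, prob = c(.5, .1, .1, .1, .1, .1)),
                       c(10, 10, 10)))
  n_spine <- sum(imgData(lm) == 1)
  n_sacrum <- sum(imgData(lm) == 5)
  comb <- combineROIs(lm, c("spine", "sacrum"))
  expect_identical(sum(comb), n_spine + n_sacrum)
  expect_identical(sum(combineROIs(lm, integer())), 0L)
  expect_identical(combineROIs(lm, c("ppj", "sacrum")),
                   combineROIs(lm, "ppj") | combineROIs(lm, "sacrum"))
  expect_error(combineROIs(lm, 9L), "unknown label")
  expect_error(combineROIs(lm, "skull"), "unknown ROI")
})

test_that("manifest reading validates schema and duplicates", {
  f <- tempfile(fileext = ".csv")
  write.csv(data.frame(subject_id = c("a", "a"), sex = "female",
                       day = c(0, 0), pet_path = "p", ct_path = "c",
                       labels_path = "l"), f, row.names = FALSE)
  expect_error(readManifest(f), "duplicate")
  write.csv(data.frame(subject_id = "a", day = 0), f, row.names = FALSE)
  expect_error(readManifest(f), "missing column")
})
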