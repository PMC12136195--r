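# Excretion-spillover detection and mask growth.

.mkSUV <- function(arr, spacing = c(0.5, 0.5, 0.5))
  ImageVolume(arr, spacing = spacing, modality = "SUV")

.mkLabels <- function(arr, spacing = c(0.5, 0.5, 0.5))
  LabelMap(arr, spacing = spacing)

test_that("background statistics exclude the padded ROI exactly", {
  d <- c(6, 6, 6)
  suv <- .mkSUV(array(0.5, d))
  lm <- .mkLabels(array(0L, d))
  st <- backgroundStats(suv, lm, 1)
  expect_equal(st$mean, 0.5)
  expect_equal(st$std, 0)

  # ROI = central 2^3 block, pad 1 -> excluded set is the central 4^3
  set.seed(20)
  vals <- array(runif(prod(d)), d)
  suv2 <- .mkSUV(vals)
  lab <- array(0L, d); lab[3:4, 3:4, 3:4] <- 1L
  st2 <- backgroundStats(suv2, .mkLabels(lab), 1)
  excl <- array(FALSE, d); excl[2:5, 2:5, 2:5] <- TRUE
  expect_equal(st2$mean, mean(vals[!excl]))
  expect_equal(st2$std, sd(vals[!excl]))
  expect_equal(st2$n, prod(d) - 64L)

  lab3 <- array(1L, d); lab3[1, 1, 1] <- 0L
  expect_error(backgroundStats(suv2, .mkLabels(lab3), 1), "background")
})

test_that("uniform SUV yields no extreme regions", {
  d <- c(8, 8, 8)
  suv <- .mkSUV(array(0.4, d))
  lm <- .mkLabels(array(0L, d))
  regs <- detectExtremeRegions(suv, lm, spilloverParams(min_region_voxels = 1))
  expect_length(regs, 0)
})

test_that("synthetic hotspots are detected with accurate centers", {
  d <- c(24, 24, 24); sp <- c(0.5, 0.5, 0.5)
  set.seed(21)
  arr <- array(abs(rnorm(prod(d), 0.3, 0.05)), d)
  ctr <- function(i) (i - 1) * 0.5  # world coord of index
  idx <- arrayInd(seq_len(prod(d)), d)
  w <- (idx - 1) * 0.5
  r1 <- sqrt(rowSums(sweep(w, 2, ctr(c(7, 7, 7)))^2))
  r2 <- sqrt(rowSums(sweep(w, 2, ctr(c(18, 18, 18)))^2))
  arr[r1 < 1.2] <- 30
  arr[r2 < 1.2] <- 25
  suv <- .mkSUV(arr, sp)
  lm <- .mkLabels(array(0L, d), sp)
  regs <- detectExtremeRegions(suv, lm, spilloverParams())
  expect_length(regs, 2)
  # ordered by descending peak
  expect_gt(regs[[1]]$peak_suv, regs[[2]]$peak_suv)
  expect_lt(max(abs(regs[[1]]$center - ctr(c(7, 7, 7)))), 0.25)
  expect_lt(max(abs(regs[[2]]$center - ctr(c(18, 18, 18)))), 0.25)
  # direct thresholding oracle: region voxels = thresholded component
  thr <- attr(regs, "threshold")
  expect_setequal(regs[[1]]$voxels, which(array(r1 < 1.2, d) & arr > thr))
})

test_that("gradient of a linear ramp is exact and world-oriented", {
  d <- c(8, 8, 8); sp <- c(0.5, 0.5, 0.5)
  idx <- arrayInd(seq_len(prod(d)), d)
  ramp <- array((idx[, 1] - 1) * 0.5, d)  # SUV = x_mm
  g <- suvGradient(.mkSUV(ramp, sp), smooth_sigma_mm = 0)
  interior <- array(FALSE, d); interior[2:7, 2:7, 2:7] <- TRUE
  expect_equal(unique(round(g$gx[interior], 10)), 1)
  expect_equal(unique(round(g$gy[interior], 10)), 0)
  expect_equal(unique(round(g$gz[interior], 10)), 0)
  g0 <- suvGradient(.mkSUV(array(1, d), sp), 0)
  expect_true(all(g0$gx == 0 & g0$gy == 0 & g0$gz == 0))

  # under a rotated affine the world gradient still points along world x
  th <- 0.5
  R <- diag(3); R[1:2, 1:2] <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  A <- diag(4); A[1:3, 1:3] <- R %*% diag(sp)
  xw <- t(A[1:3, 1:3] %*% t(idx - 1))
  rampw <- array(xw[, 1], d)
  vr <- ImageVolume(rampw - min(rampw), transform = A, modality = "SUV")
  gr <- suvGradient(vr, 0)
  expect_equal(unique(round(gr$gx[interior], 8)), 1)
  expect_equal(unique(round(gr$gy[interior], 8)), 0)
})

test_that("Gaussian blob gradients point toward the blob center", {
  d <- c(16, 16, 16); sp <- c(0.5, 0.5, 0.5)
  ctr <- c(3.75, 3.75, 3.75)
  idx <- arrayInd(seq_len(prod(d)), d)
  w <- (idx - 1) * 0.5
  r2 <- rowSums(sweep(w, 2, ctr)^2)
  blob <- array(10 * exp(-r2 / 4), d)
  g <- suvGradient(.mkSUV(blob, sp), 0)
  interior <- which(array(TRUE, d) & idx[, 1] %in% 2:15 &
                    idx[, 2] %in% 2:15 & idx[, 3] %in% 2:15 & r2 > 0.1)
  toC <- sweep(w, 2, ctr, "-") * -1
  dp <- g$gx[interior] * toC[interior, 1] + g$gy[interior] * toC[interior, 2] +
        g$gz[interior] * toC[interior, 3]
  expect_true(all(dp >= -1e-10))
})

test_that("empty region list produces an all-false mask", {
  d <- c(6, 6, 6)
  suv <- .mkSUV(array(0.3, d))
  lm <- .mkLabels(array(0L, d))
  sp <- growSpilloverMask(suv, lm, list())
  expect_false(any(maskData(sp)))
  expect_true(all(removedFractions(sp) == 0))
  # applySpillover identities
  m <- array(c(TRUE, FALSE), d)
  expect_identical(applySpillover(m, sp), m)
  spAll <- new("SpilloverMask", data = array(TRUE, d),
               provenance = array(0L, d), removed_fraction = numeric(),
               regions = data.frame())
  expect_false(any(applySpillover(m, spAll)))
  expect_equal(sum(applySpillover(m, sp)), sum(m) - sum(m & maskData(sp)))
})

test_that("the separable distance transform is exact", {
  set.seed(22)
  m <- array(runif(6 * 7 * 5) < 0.12, c(6, 7, 5))
  m[3, 4, 2] <- TRUE
  sp3 <- c(0.4, 0.7, 1.1)
  d2 <- skelquant:::.edtSquared(m, sp3)
  xyz <- skelquant:::.voxelWorldCoords(arrayInd(which(m), dim(m)),
                                       diag(c(sp3, 1)))
  all_xyz <- skelquant:::.gridWorldCoords(dim(m), diag(c(sp3, 1)))
  brute <- apply(all_xyz, 1, function(p) min(colSums((t(xyz) - p)^2)))
  expect_equal(as.vector(d2), brute, tolerance = 1e-12)
})

test_that("phantom spillover mask covers the contaminated pelvis and spares clean bone", {
  ses <- smallSession(18L)
  sp <- spilloverMask(ses$pet, ses$labels)
  truth <- spilloverTruthMask(ses$truth, 0.25)
  expect_gt(sum(maskData(sp) & truth) / sum(truth), 0.8)
  clean <- (ses$truth$spill / ses$truth$total_noiseless) < 0.05
  ppj <- imgData(ses$labels) == 4L
  expect_lt(sum(maskData(sp) & clean & ppj) / sum(clean & ppj), 0.05)
  # removal never increases the ROI SUV mean (non-negative spillover)
  pet <- ses$pet; ct <- ses$ct
  before <- panelForMask(pet, ct, ppj)
  after <- panelForMask(pet, ct, ppj, sp)
  expect_lte(after$suv_mean, before$suv_mean)
})

test_that("mask growth is deterministic and local", {
  ses <- smallSession(18L)
  pars <- spilloverParams()
  regs <- detectExtremeRegions(ses$pet, ses$labels, pars)
  sp1 <- growSpilloverMask(ses$pet, ses$labels, regs, pars)
  sp2 <- growSpilloverMask(ses$pet, ses$labels, regs, pars)
  expect_identical(maskData(sp1), maskData(sp2))
  # locality: no masked voxel farther than max_growth + region diameter
  # from its source region's center
  reg <- regs[[1]]
  rx <- skelquant:::.voxelWorldCoords(arrayInd(reg$voxels,
                                               dim(imgData(ses$labels))),
                                      ses$pet@transform)
  diam <- max(sqrt(rowSums(sweep(rx, 2, reg$center)^2))) * 2
  mx <- skelquant:::.voxelWorldCoords(arrayInd(which(maskData(sp1)),
                                               dim(imgData(ses$labels))),
                                      ses$pet@transform)
  dists <- sqrt(rowSums(sweep(mx, 2, reg$center)^2))
  expect_lt(max(dists), pars$max_growth_mm + diam)
})

test_that("lowering k_sigma never shrinks the extreme-voxel set", {
  ses <- smallSession(18L)
  r3 <- detectExtremeRegions(ses$pet, ses$labels,
                             spilloverParams(k_sigma = 3))
  r2 <- detectExtremeRegions(ses$pet, ses$labels,
                             spilloverParams(k_sigma = 2))
  v3 <- sort(unlist(lapply(r3, `[[`, "voxels")))
  v2 <- sort(unlist(lapply(r2, `[[`, "voxels")))
  expect_true(all(v3 %in% v2))
})

test_that("a hotspot beyond growth reach removes nothing from any ROI", {
  d <- c(30, 30, 30); sp3 <- c(0.5, 0.5, 0.5)
  set.seed(23)
  arr <- array(abs(rnorm(prod(d), 0.3, 0.05)), d)
  idx <- arrayInd(seq_len(prod(d)), d)
  w <- (idx - 1) * 0.5
  r <- sqrt(rowSums(sweep(w, 2, c(2, 2, 2))^2))
  arr[r < 1] <- 25
  lab <- array(0L, d); lab[24:28, 24:28, 24:28] <- 4L  # far corner ROI
  suv <- .mkSUV(arr, sp3)
  lm <- .mkLabels(lab, sp3)
  spm <- spilloverMask(suv, lm)
  expect_equal(nrow(spm@regions), 1L)
  expect_true(all(removedFractions(spm) == 0))
})
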