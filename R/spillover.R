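# Excretion-spillover detection and removal.
#
# Radiotracer accumulating in urine and feces produces extreme SUV just
# outside the pelvis; its signal spills into adjacent skeletal ROIs and
# inflates their metrics. The algorithm: (1) threshold the non-ROI SUV at
# mean + k*std of the padded background, (2) take 26-connected components of
# the supra-threshold voxels as extreme regions, (3) from each region grow a
# mask over neighboring voxels whose SUV gradient points toward the region's
# geometric center (spillover decays with distance from its source, so its
# gradient points back at the source), capped at a maximum growth distance
# from the region boundary.

#' Spillover removal parameters
#'
#' @param k_sigma threshold multiplier: extreme voxels exceed
#'   mean + k_sigma * std of the background SUV (default 3, the conventional
#'   outlier cut).
#' @param pad_voxels ROI dilation radius (voxels, cube structuring element)
#'   excluded from the background statistics (default 2).
#' @param min_region_voxels minimum 26-connected component size for an
#'   extreme region (default 10; suppresses isolated noise voxels).
#' @param smooth_sigma_mm Gaussian pre-smoothing scale for gradient
#'   estimation, mm; \code{NULL} (default) uses one voxel spacing per axis;
#'   0 disables smoothing.
#' @param max_growth_mm cap on growth distance from a region's boundary
#'   (default 3 mm).
#' @return Named list of parameters.
#' @export
spilloverParams <- function(k_sigma = 3, pad_voxels = 2L,
                            min_region_voxels = 10L,
                            smooth_sigma_mm = NULL, max_growth_mm = 3) {
  stopifnot(k_sigma > 0, pad_voxels >= 0, min_region_voxels >= 1,
            is.null(smooth_sigma_mm) || smooth_sigma_mm >= 0,
            max_growth_mm > 0)
  list(k_sigma = k_sigma, pad_voxels = as.integer(pad_voxels),
       min_region_voxels = as.integer(min_region_voxels),
       smooth_sigma_mm = smooth_sigma_mm, max_growth_mm = max_growth_mm)
}

#' Background SUV statistics outside the padded ROIs
#'
#' Sample mean and sample standard deviation (ddof = 1) of SUV over voxels
#' outside the union of all ROIs dilated by \code{pad_voxels} (cube
#' structuring element, i.e. 26-connectivity per step).
#'
#' @param suv SUV \linkS4class{ImageVolume}.
#' @param labels \linkS4class{LabelMap} on the same grid.
#' @param pad_voxels dilation radius in voxels.
#' @return list(mean =, std =, n = number of background voxels).
#' @export
backgroundStats <- function(suv, labels, pad_voxels = 2L) {
  if (!identical(dim(suv@data), dim(labels@data)))
    stop("grid mismatch between suv and labels")
  roi <- labels@data > 0L
  bg <- !.dilateCube(roi, pad_voxels)
  n <- sum(bg)
  if (n < 2L) stop("no background voxels remain after padding")
  vals <- suv@data[bg]
  list(mean = mean(vals), std = stats::sd(vals), n = n)
}

#' Detect extreme-SUV regions outside the skeletal ROIs
#'
#' Thresholds non-ROI voxels at mean + k_sigma * std from
#' [backgroundStats()] and keeps 26-connected components with at least
#' \code{min_region_voxels} voxels. Each region carries its unweighted
#' geometric center (world mm) and peak SUV; regions are ordered by
#' descending peak SUV (ties broken by lexicographic center).
#'
#' @param suv SUV \linkS4class{ImageVolume}.
#' @param labels \linkS4class{LabelMap} on the same grid.
#' @param params list from [spilloverParams()].
#' @return List of regions; each is a list with elements \code{voxels}
#'   (linear indices), \code{center} (world mm), \code{peak_suv} and
#'   \code{size}. The background threshold is attached as attribute
#'   \code{"threshold"}.
#' @export
detectExtremeRegions <- function(suv, labels, params = spilloverParams()) {
  stats <- backgroundStats(suv, labels, params$pad_voxels)
  thr <- stats$mean + params$k_sigma * stats$std
  cand <- (labels@data == 0L) & (suv@data > thr)
  comps <- .connectedComponents26(cand)
  comps <- comps[vapply(comps, length, 1L) >= params$min_region_voxels]
  regions <- lapply(comps, function(vox) {
    xyz <- .voxelWorldCoords(arrayInd(vox, dim(suv@data)), suv@transform)
    list(voxels = vox, center = colMeans(xyz),
         peak_suv = max(suv@data[vox]), size = length(vox))
  })
  if (length(regions)) {
    peaks <- vapply(regions, `[[`, 0, "peak_suv")
    ctr <- t(vapply(regions, `[[`, numeric(3), "center"))
    regions <- regions[order(-peaks, ctr[, 1], ctr[, 2], ctr[, 3])]
  }
  attr(regions, "threshold") <- thr
  regions
}

#' SUV gradient field in world coordinates
#'
#' Gaussian-smooths the SUV volume (skipped when the scale is 0), takes
#' central differences along each index axis, and rotates the index-space
#' gradient into the world frame through the affine, so components are in
#' SUV per mm regardless of voxel anisotropy or grid orientation.
#'
#' @param suv SUV \linkS4class{ImageVolume}, at least 3 voxels per axis.
#' @param smooth_sigma_mm smoothing scale in mm; \code{NULL} = one voxel.
#' @return list of three 3D arrays (gx, gy, gz), world-mm components.
#' @export
suvGradient <- function(suv, smooth_sigma_mm = NULL) {
  d <- dim(suv@data)
  if (any(d < 3)) stop("volume too small for central differences")
  sp <- suv@spacing
  if (is.null(smooth_sigma_mm)) sigma_vox <- c(1, 1, 1)
  else sigma_vox <- smooth_sigma_mm / sp
  a <- if (all(sigma_vox <= 0)) suv@data else .gaussSmooth(suv@data, sigma_vox)
  gi <- vector("list", 3)
  for (axis in 1:3) {
    fwd <- .shiftArray(a, axis, -1)  # value at index+1
    bwd <- .shiftArray(a, axis, 1)   # value at index-1
    g <- (fwd - bwd) / 2
    # one-sided at the faces
    n <- d[axis]
    if (axis == 1) { g[1, , ] <- a[2, , ] - a[1, , ]; g[n, , ] <- a[n, , ] - a[n - 1, , ] }
    if (axis == 2) { g[, 1, ] <- a[, 2, ] - a[, 1, ]; g[, n, ] <- a[, n, ] - a[, n - 1, ] }
    if (axis == 3) { g[, , 1] <- a[, , 2] - a[, , 1]; g[, , n] <- a[, , n] - a[, , n - 1] }
    gi[[axis]] <- g
  }
  # dS/dworld = A3^{-T} dS/dindex
  B <- t(solve(suv@transform[1:3, 1:3]))
  list(gx = B[1, 1] * gi[[1]] + B[1, 2] * gi[[2]] + B[1, 3] * gi[[3]],
       gy = B[2, 1] * gi[[1]] + B[2, 2] * gi[[2]] + B[2, 3] * gi[[3]],
       gz = B[3, 1] * gi[[1]] + B[3, 2] * gi[[2]] + B[3, 3] * gi[[3]])
}

#' Grow the spillover exclusion mask from extreme regions
#'
#' Each region's own voxels seed the mask. Growth proceeds over 26-neighbors
#' (frontier-synchronous, so the result is order-independent): a voxel v is
#' added iff (a) its SUV gradient has positive dot product with the vector
#' from v to the region center (the gradient points toward the source),
#' (b) v lies within \code{max_growth_mm} of the region's boundary, and
#' (c) v is not already claimed by a region with higher peak SUV. ROI
#' membership does not block growth - spillover may invade the skeleton,
#' which is exactly the contamination being removed.
#'
#' @param suv SUV \linkS4class{ImageVolume}.
#' @param labels \linkS4class{LabelMap} on the same grid.
#' @param regions output of [detectExtremeRegions()] on the same grids.
#' @param params list from [spilloverParams()].
#' @return A \linkS4class{SpilloverMask} with per-ROI removed fractions.
#' @export
growSpilloverMask <- function(suv, labels, regions,
                              params = spilloverParams()) {
  dims <- dim(suv@data)
  if (!identical(dims, dim(labels@data)))
    stop("grid mismatch between suv and labels")
  mask <- array(FALSE, dims)
  prov <- array(0L, dims)
  regdf <- data.frame(rank = integer(), center_x = numeric(),
                      center_y = numeric(), center_z = numeric(),
                      peak_suv = numeric(), size = integer(),
                      grown_size = integer())
  if (length(regions)) {
    grad <- suvGradient(suv, params$smooth_sigma_mm)
    growth_r_vox <- ceiling(params$max_growth_mm / suv@spacing) + 1L
    for (ri in seq_along(regions)) {
      reg <- regions[[ri]]
      seedIdx <- reg$voxels
      seedIjk <- arrayInd(seedIdx, dims)
      inSeed <- array(FALSE, dims); inSeed[seedIdx] <- TRUE
      # candidate bounding box around the seed
      lo <- pmax(apply(seedIjk, 2, min) - growth_r_vox, 1L)
      hi <- pmin(apply(seedIjk, 2, max) + growth_r_vox, dims)
      bi <- lo[1]:hi[1]; bj <- lo[2]:hi[2]; bk <- lo[3]:hi[3]
      boxDim <- c(length(bi), length(bj), length(bk))
      seedBox <- inSeed[bi, bj, bk, drop = FALSE]
      # exact distance to the region (= to its boundary, for outside
      # voxels) via a separable Euclidean distance transform
      d2 <- .edtSquared(seedBox, suv@spacing)
      dokBox <- d2 <= params$max_growth_mm^2 & !seedBox
      candBox <- which(dokBox & !mask[bi, bj, bk])
      if (length(candBox)) {
        candIjk <- arrayInd(candBox, boxDim)
        candIjk[, 1] <- candIjk[, 1] + lo[1] - 1L
        candIjk[, 2] <- candIjk[, 2] + lo[2] - 1L
        candIjk[, 3] <- candIjk[, 3] + lo[3] - 1L
        candLin <- (candIjk[, 3] - 1L) * (dims[1] * dims[2]) +
                   (candIjk[, 2] - 1L) * dims[1] + candIjk[, 1]
        candXyz <- .voxelWorldCoords(candIjk, suv@transform)
        toC <- cbind(reg$center[1] - candXyz[, 1],
                     reg$center[2] - candXyz[, 2],
                     reg$center[3] - candXyz[, 3])
        dp <- grad$gx[candLin] * toC[, 1] + grad$gy[candLin] * toC[, 2] +
              grad$gz[candLin] * toC[, 3]
        eligible <- array(FALSE, dims)
        eligible[candLin[dp > 0]] <- TRUE
      } else {
        eligible <- array(FALSE, dims)
      }
      visited <- inSeed
      frontier <- seedIdx
      while (length(frontier)) {
        nb <- .neighbors26(frontier, dims)
        nb <- nb[eligible[nb] & !visited[nb]]
        if (!length(nb)) break
        visited[nb] <- TRUE
        frontier <- nb
      }
      grown <- which(visited & !mask)
      mask[grown] <- TRUE
      prov[grown] <- ri
      regdf <- rbind(regdf, data.frame(
        rank = ri, center_x = reg$center[1], center_y = reg$center[2],
        center_z = reg$center[3], peak_suv = reg$peak_suv,
        size = reg$size, grown_size = length(grown)))
    }
  }
  lab <- roiLabels()[-1]
  rf <- vapply(lab, function(l) {
    inRoi <- labels@data == l
    n <- sum(inRoi)
    if (n == 0L) return(0)
    sum(mask & inRoi) / n
  }, numeric(1))
  names(rf) <- names(lab)
  new("SpilloverMask", data = mask, provenance = prov,
      removed_fraction = rf, regions = regdf)
}

#' Detect and grow the spillover mask in one call
#'
#' @inheritParams growSpilloverMask
#' @return A \linkS4class{SpilloverMask}.
#' @export
spilloverMask <- function(suv, labels, params = spilloverParams()) {
  growSpilloverMask(suv, labels,
                    detectExtremeRegions(suv, labels, params), params)
}

#' Exclude spillover voxels from an ROI mask
#'
#' @param mask_roi logical 3D ROI mask.
#' @param spill a \linkS4class{SpilloverMask} on the same grid.
#' @return \code{mask_roi & !spill}; always a subset of \code{mask_roi}.
#' @export
applySpillover <- function(mask_roi, spill) {
  if (!identical(dim(mask_roi), dim(spill@data)))
    stop("grid mismatch between ROI mask and spillover mask")
  mask_roi & !spill@data
}
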