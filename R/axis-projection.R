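# PCA long-axis fitting and perpendicular slicing of individual bones.
#
# Assuming the bone's shape is stable over time, the first principal
# component of its voxel coordinates (world mm, unweighted) estimates the
# bone's longitudinal direction. Each voxel is mapped to its scalar
# projection t along that axis and binned into slices perpendicular to it,
# giving location-resolved SUV/HU profiles that are comparable across scans
# without non-rigid registration. The spine is deliberately excluded: it is
# curved and changes shape with posture, so a straight principal axis is
# not meaningful there.

#' Fit a bone's long axis by PCA
#'
#' Centroid = mean of member voxel world coordinates; direction = unit
#' eigenvector of the coordinate covariance with the largest eigenvalue;
#' explained variance ratio = lambda1 / sum(lambda). A near-isotropic voxel
#' cloud (no clearly dominant component) is returned with
#' \code{stable = FALSE}: the direction is then arbitrary.
#'
#' @param mask logical 3D array (>= 3 non-collinear voxels).
#' @param transform 4x4 affine, 0-based index to world mm.
#' @return An \linkS4class{AxisModel}.
#' @export
fitLongAxis <- function(mask, transform) {
  idx <- which(mask)
  if (length(idx) < 3L) stop("mask must contain at least 3 voxels")
  xyz <- .voxelWorldCoords(arrayInd(idx, dim(mask)), transform)
  centroid <- colMeans(xyz)
  cc <- sweep(xyz, 2, centroid)
  cv <- crossprod(cc) / (nrow(cc) - 1)
  eg <- eigen(cv, symmetric = TRUE)
  ev <- pmax(eg$values, 0)
  tot <- sum(ev)
  if (tot < 1e-12) stop("degenerate voxel set: all coordinates identical")
  evr <- ev[1] / tot
  dir <- eg$vectors[, 1]
  dir <- dir / sqrt(sum(dir^2))
  # dominance margin between first and second eigenvalue flags stability
  stable <- (ev[1] - ev[2]) / tot > 0.05
  new("AxisModel", direction = dir, centroid = centroid,
      explained_variance_ratio = evr, stable = stable)
}

#' Fix the sign of a PCA axis
#'
#' PCA directions are sign-ambiguous; cross-timepoint comparison needs a
#' consistent orientation. With a reference axis the direction is flipped
#' iff its dot product with the reference is negative; without one, it is
#' flipped so that the largest-magnitude world component is positive (ties
#' broken in x, y, z order).
#'
#' @param axis an \linkS4class{AxisModel}.
#' @param reference optional \linkS4class{AxisModel} (e.g. the baseline
#'   scan's axis).
#' @return The oriented \linkS4class{AxisModel}.
#' @export
orientAxis <- function(axis, reference = NULL) {
  d <- axis@direction
  if (!is.null(reference)) {
    if (sum(d * reference@direction) < 0) d <- -d
  } else {
    mags <- abs(d)
    comp <- which(mags == max(mags))[1]
    if (d[comp] < 0) d <- -d
  }
  initialize(axis, direction = d)
}

#' Assign bone voxels to slices along the long axis
#'
#' Each member voxel gets t(v) = dot(x(v) - centroid, direction). In
#' \code{per_scan} mode, \code{n_bins} equal-width bins span [min t, max t]
#' (last bin right-closed); in \code{fixed_edges} mode the caller supplies
#' the edges (typically from the subject's baseline scan) so slices align
#' across timepoints, and voxels outside the supplied range are clamped
#' into the terminal bins.
#'
#' @param mask logical 3D bone mask.
#' @param axis oriented \linkS4class{AxisModel}.
#' @param n_bins number of slices (>= 2); ignored in fixed_edges mode.
#' @param transform 4x4 affine of the grid.
#' @param mode "per_scan" or "fixed_edges".
#' @param edges strictly increasing bin edges for fixed_edges mode.
#' @return A \linkS4class{SliceProfile} skeleton (no metrics yet).
#' @export
assignSlices <- function(mask, axis, n_bins = 40L, transform,
                         mode = c("per_scan", "fixed_edges"), edges = NULL) {
  mode <- match.arg(mode)
  idx <- which(mask)
  if (!length(idx)) stop("empty mask")
  ijk <- arrayInd(idx, dim(mask))
  xyz <- .voxelWorldCoords(ijk, transform)
  tv <- (xyz[, 1] - axis@centroid[1]) * axis@direction[1] +
        (xyz[, 2] - axis@centroid[2]) * axis@direction[2] +
        (xyz[, 3] - axis@centroid[3]) * axis@direction[3]
  if (mode == "per_scan") {
    if (n_bins < 2L) stop("n_bins must be >= 2")
    rng <- range(tv)
    if (diff(rng) < 1e-9)
      stop("degenerate projection: all voxels share one slice")
    edges <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  } else {
    if (is.null(edges) || any(diff(edges) <= 0))
      stop("fixed_edges mode needs strictly increasing edges")
  }
  nb <- length(edges) - 1L
  bin <- findInterval(tv, edges, rightmost.closed = TRUE, all.inside = TRUE)
  counts <- tabulate(bin, nbins = nb)
  new("SliceProfile", bin_edges = edges, assignment = as.integer(bin),
      voxels = ijk, voxel_counts = as.integer(counts),
      metrics = data.frame(), axis = axis, mode = mode)
}

#' Compute per-slice SUV/HU metrics
#'
#' Evaluates the [panelForMask()] metric panel over each non-empty bin's
#' surviving voxels (after optional spillover exclusion). Empty bins are
#' flagged, never zero-filled.
#'
#' @param pet SUV \linkS4class{ImageVolume}.
#' @param ct HU \linkS4class{ImageVolume} on the same grid.
#' @param profile \linkS4class{SliceProfile} skeleton from [assignSlices()].
#' @param spill optional \linkS4class{SpilloverMask}.
#' @param threshold SUV exceedance threshold (default 2.5).
#' @return The \linkS4class{SliceProfile} with its metrics table filled:
#'   columns bin_index, t_center_mm, t_center_norm, voxel_count, empty,
#'   then the SUV/HU panel columns.
#' @export
sliceMetrics <- function(pet, ct, profile, spill = NULL, threshold = 2.5) {
  dims <- dim(pet@data)
  if (!identical(dims, dim(ct@data))) stop("grid mismatch between pet and ct")
  edges <- profile@bin_edges
  nb <- length(edges) - 1L
  centers <- (edges[-1] + edges[-length(edges)]) / 2
  tnorm <- (centers - edges[1]) / (edges[length(edges)] - edges[1])
  lin <- (profile@voxels[, 3] - 1L) * (dims[1] * dims[2]) +
         (profile@voxels[, 2] - 1L) * dims[1] + profile@voxels[, 1]
  keep <- rep(TRUE, length(lin))
  if (!is.null(spill)) {
    if (!identical(dims, dim(spill@data)))
      stop("grid mismatch with spillover mask")
    keep <- !spill@data[lin]
  }
  rows <- vector("list", nb)
  for (b in seq_len(nb)) {
    sel <- lin[profile@assignment == b & keep]
    if (!length(sel)) {
      rows[[b]] <- data.frame(
        bin_index = b, t_center_mm = centers[b], t_center_norm = tnorm[b],
        voxel_count = 0L, empty = TRUE,
        suv_mean = NA_real_, suv_median = NA_real_, suv_q75 = NA_real_,
        suv_q90 = NA_real_, suv_q95 = NA_real_, suv_max = NA_real_,
        suv_std = NA_real_, frac_suv_gt_thr = NA_real_, hu_mean = NA_real_,
        hu_max = NA_real_, hu_std = NA_real_, frac_hu_300_800 = NA_real_,
        frac_hu_gt_1000 = NA_real_)
      next
    }
    s <- suvPanel(pet@data[sel], threshold)
    h <- huPanel(ct@data[sel])
    rows[[b]] <- data.frame(
      bin_index = b, t_center_mm = centers[b], t_center_norm = tnorm[b],
      voxel_count = length(sel), empty = FALSE,
      suv_mean = s$mean, suv_median = s$median, suv_q75 = s$q75,
      suv_q90 = s$q90, suv_q95 = s$q95, suv_max = s$max, suv_std = s$std,
      frac_suv_gt_thr = s$frac_gt, hu_mean = h$mean, hu_max = h$max,
      hu_std = h$std, frac_hu_300_800 = h$frac_band_300_800,
      frac_hu_gt_1000 = h$frac_gt_1000)
  }
  metrics <- do.call(rbind, rows)
  # counts reflect surviving voxels so they sum to the post-exclusion mask
  initialize(profile, metrics = metrics,
             voxel_counts = as.integer(metrics$voxel_count),
             assignment = profile@assignment[keep],
             voxels = profile@voxels[keep, , drop = FALSE])
}

#' Select an axial segment of a sliced bone
#'
#' Returns the union of voxels in bins whose normalized centers fall inside
#' [a, b] (normalized position = (t - t_min)/(t_max - t_min) over the
#' profile's edge span). With fixed-edges binning the same [a, b] selects
#' the same anatomical segment at every timepoint of a subject, which is
#' how the acetabular segment is defined reproducibly.
#'
#' @param profile a \linkS4class{SliceProfile}.
#' @param t_range numeric(2), 0 <= a < b <= 1.
#' @param dims grid dimensions for the returned mask.
#' @return Logical 3D array over the selected voxels.
#' @export
selectSegment <- function(profile, t_range, dims) {
  a <- t_range[1]; b <- t_range[2]
  if (!(a >= 0 && a < b && b <= 1)) stop("need 0 <= a < b <= 1")
  edges <- profile@bin_edges
  centers <- (edges[-1] + edges[-length(edges)]) / 2
  tnorm <- (centers - edges[1]) / (edges[length(edges)] - edges[1])
  bins <- which(tnorm >= a & tnorm <= b)
  sel <- profile@assignment %in% bins
  if (!any(sel)) stop("empty segment selection")
  out <- array(FALSE, dims)
  vox <- profile@voxels[sel, , drop = FALSE]
  out[(vox[, 3] - 1L) * (dims[1] * dims[2]) + (vox[, 2] - 1L) * dims[1] +
      vox[, 1]] <- TRUE
  out
}

#' Long-axis profile for one ROI of a session
#'
#' Convenience wrapper: combine the ROI labels, fit and orient the axis,
#' assign slices and compute metrics. Projection of the spine is refused
#' unless \code{allow_spine = TRUE}, because a straight principal axis is
#' not meaningful for a curved, posture-dependent structure.
#'
#' @param session a \linkS4class{ScanSession}.
#' @param roi ROI name(s) from [roiLabels()] (combined when several).
#' @param n_bins number of slices (default 40).
#' @param spill optional \linkS4class{SpilloverMask}.
#' @param reference_axis optional \linkS4class{AxisModel} used to orient the
#'   fitted axis consistently across timepoints.
#' @param edges optional fixed bin edges (switches to fixed_edges mode).
#' @param threshold SUV exceedance threshold.
#' @param allow_spine set TRUE to force projection of the spine.
#' @return A \linkS4class{SliceProfile} with metrics.
#' @export
projectROI <- function(session, roi, n_bins = 40L, spill = NULL,
                       reference_axis = NULL, edges = NULL, threshold = 2.5,
                       allow_spine = FALSE) {
  if ("spine" %in% roi) {
    if (!allow_spine)
      stop("long-axis projection of the spine is not supported (curved, ",
           "posture-dependent); pass allow_spine = TRUE to override")
    warning("projecting the spine: the straight-axis assumption is violated ",
            "for curved structures")
  }
  mask <- combineROIs(session@labels, roi)
  axis <- orientAxis(fitLongAxis(mask, session@labels@transform),
                     reference_axis)
  prof <- assignSlices(mask, axis, n_bins, session@labels@transform,
                       mode = if (is.null(edges)) "per_scan" else "fixed_edges",
                       edges = edges)
  sliceMetrics(session@pet, session@ct, prof, spill, threshold)
}
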