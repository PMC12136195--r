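#' @import methods
NULL

#' Skeletal ROI label convention
#'
#' The fixed integer coding used by every label map in the package:
#' 0 background, 1 spine, 2 right femoral body, 3 left femoral body,
#' 4 pelvis & pelvic joints (PPJ), 5 sacrum. The five bone labels are
#' disjoint by construction; the sacrum may be pooled with the spine or
#' the PPJ downstream via [combineROIs()].
#'
#' @return Named integer vector mapping ROI names to label ids.
#' @export
#' @examples
#' roiLabels()
roiLabels <- function() {
  c(background = 0L, spine = 1L, femur_r = 2L, femur_l = 3L,
    ppj = 4L, sacrum = 5L)
}

.VALID_MODALITIES <- c("SUV", "HU", "ACTIVITY")

#' ImageVolume: a 3D scalar image with grid geometry
#'
#' A 3D voxel lattice together with its voxel spacing (mm), the affine
#' mapping 0-based voxel indices to world coordinates in mm, and a
#' modality tag (\code{"SUV"}, \code{"HU"} or \code{"ACTIVITY"}).
#' All geometric computation in the package (centroids, PCA axes,
#' gradients) happens in world mm through the affine, so anisotropic
#' voxels are handled correctly.
#'
#' @slot data 3D numeric array of voxel values.
#' @slot spacing numeric(3), per-axis voxel size in mm (all > 0).
#' @slot transform 4x4 affine matrix, 0-based index -> world mm.
#' @slot modality one of "SUV", "HU", "ACTIVITY".
#' @export
setClass("ImageVolume",
  representation(data = "array", spacing = "numeric",
                 transform = "matrix", modality = "character"))

setValidity("ImageVolume", function(object) {
  msgs <- character()
  if (length(dim(object@data)) != 3L)
    msgs <- c(msgs, "data must be a 3D array")
  if (length(object@spacing) != 3L || any(object@spacing <= 0))
    msgs <- c(msgs, "spacing must be 3 positive values")
  if (!all(dim(object@transform) == c(4L, 4L)))
    msgs <- c(msgs, "transform must be a 4x4 matrix")
  else if (abs(det(object@transform)) < 1e-12)
    msgs <- c(msgs, "transform must be invertible")
  if (!(object@modality %in% .VALID_MODALITIES))
    msgs <- c(msgs, sprintf("modality must be one of %s",
                            paste(.VALID_MODALITIES, collapse = ", ")))
  if (object@modality == "HU" && any(object@data < -1024 - 1e-6, na.rm = TRUE))
    msgs <- c(msgs, "HU volumes admit values >= -1024")
  if (object@modality == "SUV" && any(object@data < -1e-9, na.rm = TRUE))
    msgs <- c(msgs, "SUV volumes admit values >= 0")
  if (length(msgs)) msgs else TRUE
})

#' Construct an ImageVolume
#'
#' @param data 3D numeric array.
#' @param spacing numeric(3) voxel size in mm; ignored (re-derived) when
#'   \code{transform} is supplied.
#' @param transform optional 4x4 affine (0-based index to world mm);
#'   defaults to \code{diag(spacing)} with zero origin.
#' @param modality "SUV", "HU" or "ACTIVITY".
#' @return An \linkS4class{ImageVolume}.
#' @export
#' @examples
#' v <- ImageVolume(array(0, c(4, 4, 4)), spacing = c(0.2, 0.2, 0.2),
#'                  modality = "SUV")
ImageVolume <- function(data, spacing = c(1, 1, 1), transform = NULL,
                        modality = c("SUV", "HU", "ACTIVITY")) {
  modality <- match.arg(modality)
  if (is.null(transform)) {
    transform <- diag(4)
    transform[1:3, 1:3] <- diag(spacing, 3, 3)
  } else {
    spacing <- sqrt(colSums(transform[1:3, 1:3]^2))
  }
  new("ImageVolume", data = data, spacing = as.numeric(spacing),
      transform = transform, modality = modality)
}

#' LabelMap: multi-label skeletal ROI mask
#'
#' Integer 3D lattice on a reference grid assigning each voxel to the
#' background or one of the five skeletal ROIs (see [roiLabels()]).
#'
#' @slot data 3D integer array with values in 0..5.
#' @slot spacing numeric(3) voxel size in mm.
#' @slot transform 4x4 affine, 0-based index -> world mm.
#' @export
setClass("LabelMap",
  representation(data = "array", spacing = "numeric", transform = "matrix"))

setValidity("LabelMap", function(object) {
  msgs <- character()
  if (length(dim(object@data)) != 3L)
    msgs <- c(msgs, "data must be a 3D array")
  vals <- unique(as.integer(object@data))
  if (!all(vals %in% roiLabels()))
    msgs <- c(msgs, sprintf("unknown label ids: %s",
      paste(setdiff(vals, roiLabels()), collapse = ", ")))
  if (length(msgs)) msgs else TRUE
})

#' Construct a LabelMap
#'
#' @param data 3D integer array with values in the [roiLabels()] coding.
#' @param spacing numeric(3) voxel size in mm.
#' @param transform optional 4x4 affine; defaults to \code{diag(spacing)}.
#' @return A \linkS4class{LabelMap}.
#' @export
LabelMap <- function(data, spacing = c(1, 1, 1), transform = NULL) {
  if (is.null(transform)) {
    transform <- diag(4)
    transform[1:3, 1:3] <- diag(spacing, 3, 3)
  } else {
    spacing <- sqrt(colSums(transform[1:3, 1:3]^2))
  }
  storage.mode(data) <- "integer"
  new("LabelMap", data = data, spacing = as.numeric(spacing),
      transform = transform)
}

#' ScanSession: one subject at one imaging day
#'
#' Bundles the co-registered PET (SUV) and CT (HU) volumes, the skeletal
#' label map, and the cohort metadata (subject, sex, day post-implantation;
#' day 0 is the pre-tumor baseline - each subject serves as its own control).
#'
#' @slot subject_id character scalar.
#' @slot sex "female" or "male".
#' @slot day integer >= 0 days post-implantation.
#' @slot pet \linkS4class{ImageVolume} with modality "SUV".
#' @slot ct \linkS4class{ImageVolume} with modality "HU".
#' @slot labels \linkS4class{LabelMap} on the CT grid.
#' @export
setClass("ScanSession",
  representation(subject_id = "character", sex = "character",
                 day = "integer", pet = "ImageVolume", ct = "ImageVolume",
                 labels = "LabelMap"))

setValidity("ScanSession", function(object) {
  msgs <- character()
  if (!(object@sex %in% c("female", "male")))
    msgs <- c(msgs, "sex must be 'female' or 'male'")
  if (object@day < 0L) msgs <- c(msgs, "day must be >= 0")
  if (object@pet@modality != "SUV") msgs <- c(msgs, "pet must be SUV")
  if (object@ct@modality != "HU") msgs <- c(msgs, "ct must be HU")
  if (!identical(dim(object@ct@data), dim(object@labels@data)))
    msgs <- c(msgs, "labels grid must match the CT grid")
  if (length(msgs)) msgs else TRUE
})

#' Construct a ScanSession
#'
#' @param subject_id subject identifier.
#' @param sex "female" or "male".
#' @param day integer imaging day (0 = baseline).
#' @param pet SUV \linkS4class{ImageVolume}.
#' @param ct HU \linkS4class{ImageVolume}.
#' @param labels \linkS4class{LabelMap} on the CT grid.
#' @return A \linkS4class{ScanSession}.
#' @export
ScanSession <- function(subject_id, sex, day, pet, ct, labels) {
  new("ScanSession", subject_id = as.character(subject_id), sex = sex,
      day = as.integer(day), pet = pet, ct = ct, labels = labels)
}

#' SpilloverMask: voxels excluded as excretion spillover
#'
#' @slot data logical 3D array; TRUE marks excluded voxels.
#' @slot provenance integer 3D array attributing each masked voxel to the
#'   extreme region (1-based rank by descending peak SUV) that claimed it.
#' @slot removed_fraction named numeric, per-ROI fraction of voxels masked.
#' @slot regions data.frame of detected regions (center, peak SUV, size).
#' @export
setClass("SpilloverMask",
  representation(data = "array", provenance = "array",
                 removed_fraction = "numeric", regions = "data.frame"))

setValidity("SpilloverMask", function(object) {
  msgs <- character()
  if (!is.logical(object@data)) msgs <- c(msgs, "data must be logical")
  if (length(object@removed_fraction) &&
      (any(object@removed_fraction < 0) || any(object@removed_fraction > 1)))
    msgs <- c(msgs, "removed fractions must lie in [0, 1]")
  if (length(msgs)) msgs else TRUE
})

#' AxisModel: a bone's fitted long axis
#'
#' First principal component of the bone's voxel coordinates in world mm:
#' a unit direction vector, the voxel centroid, and the fraction of
#' coordinate variance captured by the first component.
#'
#' @slot direction unit numeric(3) in world mm.
#' @slot centroid numeric(3) world-mm point.
#' @slot explained_variance_ratio first-eigenvalue share in [0, 1].
#' @slot stable logical; FALSE when the first component is not clearly
#'   dominant (near-isotropic voxel cloud) and the direction is arbitrary.
#' @export
setClass("AxisModel",
  representation(direction = "numeric", centroid = "numeric",
                 explained_variance_ratio = "numeric", stable = "logical"))

setValidity("AxisModel", function(object) {
  msgs <- character()
  if (abs(sqrt(sum(object@direction^2)) - 1) > 1e-9)
    msgs <- c(msgs, "direction must be a unit vector")
  evr <- object@explained_variance_ratio
  if (evr < -1e-12 || evr > 1 + 1e-12)
    msgs <- c(msgs, "explained_variance_ratio must lie in [0, 1]")
  if (length(msgs)) msgs else TRUE
})

#' SliceProfile: per-bin metrics along a bone's long axis
#'
#' @slot bin_edges strictly increasing projections (mm along the axis,
#'   relative to the centroid).
#' @slot assignment integer vector, bin index of each member voxel (parallel
#'   to \code{voxels}).
#' @slot voxels integer matrix of member voxel indices (1-based, n x 3).
#' @slot voxel_counts integer per-bin counts (sums to the mask size).
#' @slot metrics data.frame of per-bin metrics; empty bins carry NA rows and
#'   are flagged in \code{metrics$empty}.
#' @slot axis the \linkS4class{AxisModel} used.
#' @slot mode "per_scan" or "fixed_edges".
#' @export
setClass("SliceProfile",
  representation(bin_edges = "numeric", assignment = "integer",
                 voxels = "matrix", voxel_counts = "integer",
                 metrics = "data.frame", axis = "AxisModel", mode = "character"))

setValidity("SliceProfile", function(object) {
  msgs <- character()
  if (any(diff(object@bin_edges) <= 0))
    msgs <- c(msgs, "bin_edges must be strictly increasing")
  if (sum(object@voxel_counts) != length(object@assignment))
    msgs <- c(msgs, "voxel_counts must sum to the number of member voxels")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "ImageVolume", function(object) {
  d <- dim(object@data)
  cat(sprintf("ImageVolume [%s]: %d x %d x %d, spacing %.3g x %.3g x %.3g mm\n",
              object@modality, d[1], d[2], d[3],
              object@spacing[1], object@spacing[2], object@spacing[3]))
  cat(sprintf("  value range: [%.4g, %.4g]\n",
              min(object@data), max(object@data)))
})

setMethod("show", "LabelMap", function(object) {
  d <- dim(object@data)
  cat(sprintf("LabelMap: %d x %d x %d\n", d[1], d[2], d[3]))
  tab <- table(factor(object@data, levels = roiLabels(),
                      labels = names(roiLabels())))
  for (nm in names(tab)) cat(sprintf("  %-10s %d\n", nm, tab[[nm]]))
})

setMethod("show", "SpilloverMask", function(object) {
  cat(sprintf("SpilloverMask: %d voxels excluded, %d source region(s)\n",
              sum(object@data), nrow(object@regions)))
  if (length(object@removed_fraction)) {
    for (nm in names(object@removed_fraction))
      cat(sprintf("  %-10s %.2f%% removed\n", nm,
                  100 * object@removed_fraction[[nm]]))
  }
})

setMethod("show", "AxisModel", function(object) {
  cat(sprintf(
    "AxisModel: direction (%.3f, %.3f, %.3f), EVR %.3f%s\n",
    object@direction[1], object@direction[2], object@direction[3],
    object@explained_variance_ratio,
    if (object@stable) "" else " [unstable]"))
})

setMethod("show", "SliceProfile", function(object) {
  cat(sprintf("SliceProfile: %d bins (%s), %d voxels, %d empty bin(s)\n",
              length(object@voxel_counts), object@mode,
              sum(object@voxel_counts), sum(object@voxel_counts == 0L)))
})

# ---- accessors -------------------------------------------------------------

#' @rdname ImageVolume-class
#' @param x an ImageVolume, LabelMap or related object.
#' @export
setGeneric("imgData", function(x) standardGeneric("imgData"))

#' @rdname ImageVolume-class
#' @export
setMethod("imgData", "ImageVolume", function(x) x@data)

#' @rdname LabelMap-class
#' @param x a LabelMap.
#' @export
setMethod("imgData", "LabelMap", function(x) x@data)

#' @rdname ImageVolume-class
#' @export
setGeneric("voxelSpacing", function(x) standardGeneric("voxelSpacing"))

#' @rdname ImageVolume-class
#' @export
setMethod("voxelSpacing", "ImageVolume", function(x) x@spacing)

#' @rdname LabelMap-class
#' @export
setMethod("voxelSpacing", "LabelMap", function(x) x@spacing)

#' @rdname ImageVolume-class
#' @export
setGeneric("worldTransform", function(x) standardGeneric("worldTransform"))

#' @rdname ImageVolume-class
#' @export
setMethod("worldTransform", "ImageVolume", function(x) x@transform)

#' @rdname LabelMap-class
#' @export
setMethod("worldTransform", "LabelMap", function(x) x@transform)

#' @rdname AxisModel-class
#' @param x an AxisModel.
#' @export
setGeneric("axisDirection", function(x) standardGeneric("axisDirection"))

#' @rdname AxisModel-class
#' @export
setMethod("axisDirection", "AxisModel", function(x) x@direction)

#' @rdname AxisModel-class
#' @export
setGeneric("axisCentroid", function(x) standardGeneric("axisCentroid"))

#' @rdname AxisModel-class
#' @export
setMethod("axisCentroid", "AxisModel", function(x) x@centroid)

#' @rdname SpilloverMask-class
#' @param x a SpilloverMask.
#' @export
setGeneric("maskData", function(x) standardGeneric("maskData"))

#' @rdname SpilloverMask-class
#' @export
setMethod("maskData", "SpilloverMask", function(x) x@data)

#' @rdname SpilloverMask-class
#' @export
setGeneric("removedFractions", function(x) standardGeneric("removedFractions"))

#' @rdname SpilloverMask-class
#' @export
setMethod("removedFractions", "SpilloverMask", function(x) x@removed_fraction)

#' @rdname SliceProfile-class
#' @param x a SliceProfile.
#' @export
setGeneric("profileMetrics", function(x) standardGeneric("profileMetrics"))

#' @rdname SliceProfile-class
#' @export
setMethod("profileMetrics", "SliceProfile", function(x) x@metrics)

#' @rdname SliceProfile-class
#' @export
setGeneric("voxelCounts", function(x) standardGeneric("voxelCounts"))

#' @rdname SliceProfile-class
#' @export
setMethod("voxelCounts", "SliceProfile", function(x) x@voxel_counts)
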