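# NIfTI I/O, grid resampling, SUV conversion, ROI combination.

.affineFromNifti <- function(img) {
  m <- unclass(RNifti::xform(img))
  attributes(m) <- list(dim = c(4L, 4L))
  m
}

#' Read a 3D NIfTI volume
#'
#' Reads a NIfTI-1/2 image and wraps it as an [ImageVolume] with spacing and
#' world transform taken from the header (sform/qform, 0-based voxel indices
#' to world mm).
#'
#' @param path path to a .nii or .nii.gz file.
#' @param modality modality tag: "SUV", "HU" or "ACTIVITY".
#' @return An \linkS4class{ImageVolume}.
#' @export
readVolume <- function(path, modality = c("SUV", "HU", "ACTIVITY")) {
  modality <- match.arg(modality)
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3L)
    stop("expected 3D volume, got ", length(dim(img)), "D: ", path)
  aff <- .affineFromNifti(img)
  if (abs(det(aff)) < 1e-12) stop("non-invertible transform in ", path)
  ImageVolume(array(as.vector(img), dim(img)), transform = aff,
              modality = modality)
}

#' Write an ImageVolume to NIfTI
#'
#' Voxel data are stored as float32; the affine goes into the sform so
#' arbitrary (rotated, anisotropic) grids round-trip exactly.
#'
#' @param vol an \linkS4class{ImageVolume}.
#' @param path output path (.nii or .nii.gz).
#' @return \code{path}, invisibly.
#' @export
writeVolume <- function(vol, path) {
  validObject(vol)
  if (dir.exists(path)) stop("path is a directory, need a file name: ", path)
  img <- RNifti::asNifti(vol@data, datatype = "float")
  img <- RNifti::`sform<-`(img, structure(vol@transform, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a skeletal label map from NIfTI
#'
#' Files carrying label ids outside the [roiLabels()] convention are
#' rejected rather than remapped.
#'
#' @param path path to a NIfTI file with integer labels 0..5.
#' @return A \linkS4class{LabelMap}.
#' @export
readLabelMap <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3L) stop("expected 3D volume: ", path)
  dat <- array(as.vector(img), dim(img))
  ints <- round(dat)
  if (max(abs(dat - ints)) > 1e-6) stop("non-integer label values in ", path)
  LabelMap(ints, transform = .affineFromNifti(img))
}

#' Write a LabelMap to NIfTI (unsigned 8-bit)
#'
#' @param labels a \linkS4class{LabelMap}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeLabelMap <- function(labels, path) {
  img <- RNifti::asNifti(labels@data, datatype = "uint8")
  img <- RNifti::`sform<-`(img, structure(labels@transform, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

# World coordinates of all voxels of a grid, as an n x 3 matrix ordered in
# R's column-major linear index order. ijk are 0-based.
.gridWorldCoords <- function(dims, transform) {
  i <- rep.int(seq_len(dims[1]) - 1L, dims[2] * dims[3])
  j <- rep.int(rep(seq_len(dims[2]) - 1L, each = dims[1]), dims[3])
  k <- rep(seq_len(dims[3]) - 1L, each = dims[1] * dims[2])
  A <- transform
  cbind(A[1, 1] * i + A[1, 2] * j + A[1, 3] * k + A[1, 4],
        A[2, 1] * i + A[2, 2] * j + A[2, 3] * k + A[2, 4],
        A[3, 1] * i + A[3, 2] * j + A[3, 3] * k + A[3, 4])
}

# World coords of selected voxels (1-based index matrix n x 3).
.voxelWorldCoords <- function(idx, transform) {
  A <- transform
  i <- idx[, 1] - 1; j <- idx[, 2] - 1; k <- idx[, 3] - 1
  cbind(A[1, 1] * i + A[1, 2] * j + A[1, 3] * k + A[1, 4],
        A[2, 1] * i + A[2, 2] * j + A[2, 3] * k + A[2, 4],
        A[3, 1] * i + A[3, 2] * j + A[3, 3] * k + A[3, 4])
}

# Trilinear sample of a 3D array at continuous 0-based voxel coordinates.
# Out-of-grid samples get `fill`.
.sampleTrilinear <- function(arr, pts, fill) {
  d <- dim(arr)
  x <- pts[, 1]; y <- pts[, 2]; z <- pts[, 3]
  x0 <- floor(x); y0 <- floor(y); z0 <- floor(z)
  fx <- x - x0; fy <- y - y0; fz <- z - z0
  inside <- x >= 0 & x <= d[1] - 1 & y >= 0 & y <= d[2] - 1 &
            z >= 0 & z <= d[3] - 1
  out <- rep(fill, length(x))
  if (!any(inside)) return(out)
  x0 <- pmin(pmax(x0[inside], 0), d[1] - 1); fx <- fx[inside]
  y0 <- pmin(pmax(y0[inside], 0), d[2] - 1); fy <- fy[inside]
  z0 <- pmin(pmax(z0[inside], 0), d[3] - 1); fz <- fz[inside]
  x1 <- pmin(x0 + 1, d[1] - 1); y1 <- pmin(y0 + 1, d[2] - 1)
  z1 <- pmin(z0 + 1, d[3] - 1)
  lin <- function(i, j, k) arr[1 + i + d[1] * (j + d[2] * k)]
  v <- lin(x0, y0, z0) * (1 - fx) * (1 - fy) * (1 - fz) +
       lin(x1, y0, z0) * fx * (1 - fy) * (1 - fz) +
       lin(x0, y1, z0) * (1 - fx) * fy * (1 - fz) +
       lin(x1, y1, z0) * fx * fy * (1 - fz) +
       lin(x0, y0, z1) * (1 - fx) * (1 - fy) * fz +
       lin(x1, y0, z1) * fx * (1 - fy) * fz +
       lin(x0, y1, z1) * (1 - fx) * fy * fz +
       lin(x1, y1, z1) * fx * fy * fz
  out[inside] <- v
  out
}

.sampleNearest <- function(arr, pts, fill) {
  d <- dim(arr)
  x <- round(pts[, 1]); y <- round(pts[, 2]); z <- round(pts[, 3])
  inside <- x >= 0 & x <= d[1] - 1 & y >= 0 & y <= d[2] - 1 &
            z >= 0 & z <= d[3] - 1
  out <- rep(fill, nrow(pts))
  out[inside] <- arr[1 + x[inside] + d[1] * (y[inside] + d[2] * z[inside])]
  out
}

#' Resample a volume onto a reference grid
#'
#' Pulls values of \code{vol} onto the lattice of \code{reference} through
#' both affines. Voxels that map outside \code{vol} are filled with 0 for
#' SUV/ACTIVITY and -1024 for HU.
#'
#' @param vol \linkS4class{ImageVolume} or \linkS4class{LabelMap} to resample.
#' @param reference \linkS4class{ImageVolume} (or LabelMap) defining the
#'   output grid.
#' @param method "trilinear" (default for images) or "nearest" (always used
#'   for label maps).
#' @return An object of the same class as \code{vol} on the reference grid.
#' @export
resampleToGrid <- function(vol, reference, method = c("trilinear", "nearest")) {
  method <- match.arg(method)
  refDim <- dim(if (is(reference, "LabelMap")) reference@data else reference@data)
  if (any(refDim < 1)) stop("degenerate reference grid")
  refT <- reference@transform
  srcT <- vol@transform
  # continuous source voxel coords of every reference voxel
  M <- solve(srcT) %*% refT
  pts <- .gridWorldCoords(refDim, M)
  if (is(vol, "LabelMap")) {
    vals <- .sampleNearest(vol@data, pts, fill = 0L)
    return(LabelMap(array(as.integer(vals), refDim), transform = refT))
  }
  fill <- if (vol@modality == "HU") -1024 else 0
  vals <- if (method == "nearest") .sampleNearest(vol@data, pts, fill)
          else .sampleTrilinear(vol@data, pts, fill)
  if (vol@modality == "SUV") vals <- pmax(vals, 0)
  ImageVolume(array(vals, refDim), transform = refT, modality = vol@modality)
}

#' Convert an activity map to body-weight SUV
#'
#' SUV(v) = activity(v) / (decayed dose / body weight), with the usual
#' 1 g/mL tissue density so Bq/mL and Bq/g are interchangeable. The injected
#' dose is decay-corrected over \code{decay_interval} with the tracer
#' half-life before normalization.
#'
#' @param activity \linkS4class{ImageVolume} with modality "ACTIVITY", Bq/mL.
#' @param injected_dose injected activity in Bq (at injection time), > 0.
#' @param body_weight body weight in g, > 0.
#' @param decay_interval seconds between injection and scan start.
#' @param half_life tracer half-life in seconds.
#' @return An \linkS4class{ImageVolume} with modality "SUV".
#' @export
computeSUV <- function(activity, injected_dose, body_weight,
                       decay_interval = 0, half_life = 45720) {
  if (injected_dose <= 0) stop("injected_dose must be > 0")
  if (body_weight <= 0) stop("body_weight must be > 0")
  if (activity@modality != "ACTIVITY")
    stop("expected an ACTIVITY volume")
  denom <- injected_dose * 2^(-decay_interval / half_life) / body_weight
  ImageVolume(activity@data / denom, transform = activity@transform,
              modality = "SUV")
}

#' Combine ROI labels into one binary mask
#'
#' The five skeletal labels are disjoint, so the size of the combination is
#' the sum of the member sizes (e.g. sacrum pooled with spine or PPJ).
#'
#' @param labels a \linkS4class{LabelMap}.
#' @param members integer label ids or ROI names from [roiLabels()].
#' @return Logical 3D array, TRUE where the voxel label is a member.
#' @export
#' @examples
#' lm <- LabelMap(array(c(0L, 1L, 5L, 5L), c(4, 1, 1)))
#' sum(combineROIs(lm, c("spine", "sacrum")))
combineROIs <- function(labels, members) {
  lab <- roiLabels()
  if (is.character(members)) {
    unknown <- setdiff(members, names(lab))
    if (length(unknown))
      stop("unknown ROI name(s): ", paste(unknown, collapse = ", "))
    members <- lab[members]
  }
  members <- as.integer(members)
  unknown <- setdiff(members, lab)
  if (length(unknown))
    stop("unknown label id(s): ", paste(unknown, collapse = ", "))
  if (!length(members))
    return(array(FALSE, dim(labels@data)))
  array(labels@data %in% members, dim(labels@data))
}

#' Read a cohort manifest
#'
#' CSV with columns subject_id, sex, day, pet_path, ct_path, labels_path.
#' Paths are resolved relative to the manifest's directory when not absolute.
#'
#' @param path manifest CSV path.
#' @return data.frame with absolute paths.
#' @export
readManifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  man <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "sex", "day", "pet_path", "ct_path", "labels_path")
  miss <- setdiff(need, names(man))
  if (length(miss))
    stop("manifest missing column(s): ", paste(miss, collapse = ", "))
  base <- dirname(normalizePath(path))
  fix <- function(p) ifelse(grepl("^(/|[A-Za-z]:)", p), p, file.path(base, p))
  for (col in c("pet_path", "ct_path", "labels_path")) man[[col]] <- fix(man[[col]])
  if (anyDuplicated(man[c("subject_id", "day")]))
    stop("manifest has duplicate (subject_id, day) rows")
  man
}

#' Load one manifest row as a ScanSession
#'
#' @param row a single manifest row (data.frame).
#' @return A \linkS4class{ScanSession}; the PET volume is resampled onto the
#'   CT grid (trilinear) when the grids differ, since quantification runs on
#'   the CT grid where the masks are defined.
#' @export
loadSession <- function(row) {
  for (col in c("pet_path", "ct_path", "labels_path"))
    if (!file.exists(row[[col]])) stop("missing file: ", row[[col]])
  ct <- readVolume(row$ct_path, "HU")
  pet <- readVolume(row$pet_path, "SUV")
  labels <- readLabelMap(row$labels_path)
  if (!identical(dim(pet@data), dim(ct@data)) ||
      max(abs(pet@transform - ct@transform)) > 1e-6)
    pet <- resampleToGrid(pet, ct, "trilinear")
  ScanSession(row$subject_id, row$sex, row$day, pet, ct, labels)
}
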