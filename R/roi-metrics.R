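# SUV / HU metric panel over an arbitrary voxel set.

#' SUV metric sub-panel
#'
#' Sample mean; median and 75/90/95% quantiles by linear interpolation of
#' order statistics; max; sample standard deviation (ddof = 1, reported as 0
#' for n = 1); and the fraction of values strictly above \code{threshold}.
#'
#' @param values numeric vector of SUV values (>= 1 value).
#' @param threshold SUV threshold for the exceedance fraction (> 0).
#' @return Named list: mean, median, q75, q90, q95, max, std, frac_gt, n.
#' @export
#' @examples
#' suvPanel(c(1, 2, 3, 4), threshold = 2.5)
suvPanel <- function(values, threshold = 2.5) {
  if (!length(values)) stop("empty input")
  if (threshold <= 0) stop("threshold must be > 0")
  q <- unname(stats::quantile(values, c(0.5, 0.75, 0.9, 0.95), type = 7))
  list(mean = mean(values), median = q[1], q75 = q[2], q90 = q[3],
       q95 = q[4], max = max(values),
       std = if (length(values) > 1) stats::sd(values) else 0,
       frac_gt = sum(values > threshold) / length(values),
       n = length(values))
}

#' HU metric sub-panel
#'
#' Mean, max, sample std, the trabecular-band fraction (300 < HU < 800,
#' strict on both ends) and the cortical fraction (HU > 1000, strict).
#'
#' @param values numeric vector of HU values (>= 1 value).
#' @return Named list: mean, max, std, frac_band_300_800, frac_gt_1000, n.
#' @export
#' @examples
#' huPanel(c(250, 400, 600, 900, 1200))
huPanel <- function(values) {
  if (!length(values)) stop("empty input")
  list(mean = mean(values), max = max(values),
       std = if (length(values) > 1) stats::sd(values) else 0,
       frac_band_300_800 = sum(values > 300 & values < 800) / length(values),
       frac_gt_1000 = sum(values > 1000) / length(values),
       n = length(values))
}

#' Full metric panel for a voxel set
#'
#' Gathers the SUV and HU values at the voxels of \code{mask} that survive
#' the optional spillover exclusion, and evaluates [suvPanel()] and
#' [huPanel()] on them.
#'
#' @param pet SUV \linkS4class{ImageVolume}.
#' @param ct HU \linkS4class{ImageVolume} on the same grid.
#' @param mask logical 3D array selecting the ROI voxels.
#' @param spill optional \linkS4class{SpilloverMask}; masked voxels are
#'   excluded before quantification.
#' @param threshold SUV exceedance threshold (default 2.5).
#' @return One-row data.frame with columns n_voxels, suv_mean, suv_median,
#'   suv_q75, suv_q90, suv_q95, suv_max, suv_std, frac_suv_gt_thr, hu_mean,
#'   hu_max, hu_std, frac_hu_300_800, frac_hu_gt_1000, suv_threshold.
#' @export
panelForMask <- function(pet, ct, mask, spill = NULL, threshold = 2.5) {
  if (!identical(dim(pet@data), dim(ct@data)) ||
      !identical(dim(pet@data), dim(mask)))
    stop("grid mismatch between pet, ct and mask")
  keep <- mask
  if (!is.null(spill)) {
    if (!identical(dim(spill@data), dim(mask)))
      stop("grid mismatch between mask and spillover mask")
    keep <- mask & !spill@data
  }
  if (!any(keep))
    stop("mask is empty after spillover exclusion")
  s <- suvPanel(pet@data[keep], threshold)
  h <- huPanel(ct@data[keep])
  data.frame(n_voxels = s$n,
             suv_mean = s$mean, suv_median = s$median, suv_q75 = s$q75,
             suv_q90 = s$q90, suv_q95 = s$q95, suv_max = s$max,
             suv_std = s$std, frac_suv_gt_thr = s$frac_gt,
             hu_mean = h$mean, hu_max = h$max, hu_std = h$std,
             frac_hu_300_800 = h$frac_band_300_800,
             frac_hu_gt_1000 = h$frac_gt_1000,
             suv_threshold = threshold)
}

# The ROI groupings quantified by default: the five labels plus the two
# pooled rows (spine+sacrum, ppj+sacrum) reported throughout.
.defaultRoiSets <- function() {
  list(spine = "spine", femur_r = "femur_r", femur_l = "femur_l",
       ppj = "ppj", sacrum = "sacrum",
       spine_sacrum = c("spine", "sacrum"),
       ppj_sacrum = c("ppj", "sacrum"))
}

#' Metric panels for every ROI of a session
#'
#' @param session a \linkS4class{ScanSession}.
#' @param spill optional \linkS4class{SpilloverMask}.
#' @param threshold SUV exceedance threshold.
#' @param roi_sets named list of ROI-name vectors; defaults to the five
#'   single labels plus spine+sacrum and ppj+sacrum.
#' @return data.frame, one row per ROI set, with subject metadata columns.
#' @export
sessionPanels <- function(session, spill = NULL, threshold = 2.5,
                          roi_sets = .defaultRoiSets()) {
  rows <- lapply(names(roi_sets), function(nm) {
    m <- combineROIs(session@labels, roi_sets[[nm]])
    p <- panelForMask(session@pet, session@ct, m, spill, threshold)
    cbind(data.frame(subject_id = session@subject_id, sex = session@sex,
                     day = session@day, roi = nm,
                     spillover_applied = !is.null(spill)), p)
  })
  do.call(rbind, rows)
}
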