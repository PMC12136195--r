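# Cohort-level simulation studies: type-I calibration and power of the
# female-vs-male baseline-delta tests on phantom cohorts.

#' Simulate repeated phantom cohorts and collect sex-test p-values
#'
#' Generates \code{n_cohorts} independent two-sex phantom cohorts (default
#' 4 females + 4 males, half-resolution grid), runs the baseline-delta sex
#' t-test for the requested cell in each, and returns the p-values. With
#' \code{null_effect = TRUE} the sex-specific generator effects are
#' disabled, so female and male parameters are drawn from identical
#' distributions and the rejection rate at any alpha estimates the test's
#' type-I error; with the default effects enabled the rate estimates
#' power. Cohorts use zero simulated excretion (the spillover stage is a
#' proven no-op there) to keep repeated simulation affordable.
#'
#' @param n_cohorts number of independent cohorts.
#' @param seed master seed; cohort seeds are derived from it.
#' @param day day to test (must be in \code{days}).
#' @param roi ROI name, or ROI vector for combined labels.
#' @param metric panel metric name (e.g. "suv_mean", "hu_mean").
#' @param segment optional normalized axial range c(a, b); when given the
#'   test is restricted to that segment of \code{roi} via fixed-edges
#'   slicing from each subject's baseline.
#' @param null_effect disable the sex-specific generator effects.
#' @param n_per_group subjects per sex (default 4).
#' @param spacing phantom voxel size in mm (default 0.4, half resolution).
#' @param n_bins slices for segment selection.
#' @return Numeric vector of \code{n_cohorts} p-values.
#' @export
simulateSexEffectStudy <- function(n_cohorts, seed, day = 18L, roi = "ppj",
                                   metric = "suv_mean", segment = NULL,
                                   null_effect = FALSE, n_per_group = 4L,
                                   spacing = 0.4, n_bins = 40L) {
  eff <- if (null_effect)
    list(suv_mult_day18 = 1, hu_drop = 0, hu_drop_days = integer())
  else
    list(suv_mult_day18 = 1.6, hu_drop = 180, hu_drop_days = c(25L, 32L))
  bladder0 <- c(x = 0, y = 4.6, z = 3.4, peak = 0, decay = 1.5)
  proto <- phantomSpec(sex = "male", seed = 1L, spacing = spacing,
                       bladder = bladder0, sex_effects = eff)
  anatomy <- buildAnatomy(proto)
  days <- sort(unique(c(0L, day)))
  pvals <- numeric(n_cohorts)
  for (cc in seq_len(n_cohorts)) {
    specs <- cohortSpecs(n_per_group, n_per_group,
                         seed = .deriveSeed(seed, cc), spacing = spacing,
                         bladder = bladder0, sex_effects = eff)
    if (is.null(segment)) {
      roi_lin <- which(combineROIs(LabelMap(anatomy$labels), roi))
      rows <- list()
      for (id in names(specs)) for (dy in days) {
        ses <- generateSession(specs[[id]], dy, anatomy)
        s <- suvPanel(ses$pet@data[roi_lin], 2.5)
        h <- huPanel(ses$ct@data[roi_lin])
        rows[[paste0(id, "_", dy)]] <- data.frame(
          subject_id = id, sex = specs[[id]]$sex, day = dy,
          roi = paste(roi, collapse = "+"),
          suv_mean = s$mean, suv_max = s$max, hu_mean = h$mean,
          hu_std = h$std)
      }
      panels <- do.call(rbind, rows)
      deltas <- baselineDelta(panels, metrics = metric)
      pvals[cc] <- sexTTest(deltas, day, paste(roi, collapse = "+"),
                            metric)$p_value
    } else {
      sessions <- list()
      for (id in names(specs)) for (dy in days)
        sessions[[length(sessions) + 1L]] <- asScanSession(
          generateSession(specs[[id]], dy, anatomy), id,
          specs[[id]]$sex, dy)
      pvals[cc] <- segmentTTest(sessions, roi, segment, day, metric,
                                n_bins)$p_value
    }
  }
  pvals
}
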