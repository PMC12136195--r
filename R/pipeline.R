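# End-to-end orchestration: despill -> project -> quantify -> compare.

#' Convert a generated phantom session to a ScanSession
#'
#' @param ses a [generateSession()] result.
#' @param subject_id,sex,day session metadata.
#' @return A \linkS4class{ScanSession}.
#' @export
asScanSession <- function(ses, subject_id, sex, day) {
  ScanSession(subject_id, sex, day, ses$pet, ses$ct, ses$labels)
}

#' Pipeline configuration
#'
#' One serializable object holding every stage's tunables; [runPipeline()]
#' logs the fully resolved configuration with each report so runs are
#' reproducible.
#'
#' @param spillover list of [spilloverParams()] arguments plus
#'   \code{enabled}.
#' @param n_bins slices per bone profile.
#' @param profile_rois ROIs to profile (spine excluded by design).
#' @param segments named list of list(roi =, range = c(a, b)) axial
#'   segments to test (default: the acetabular segment of the PPJ).
#' @param suv_threshold SUV exceedance threshold (default 2.5).
#' @param test_var_equal use pooled-variance t-tests (default FALSE =
#'   Welch).
#' @param p_adjust p-value adjustment method ("none" by default).
#' @param seed integer seed recorded with the run.
#' @return Named list.
#' @export
pipelineConfig <- function(spillover = list(enabled = TRUE, k_sigma = 3,
                                            pad_voxels = 2,
                                            min_region_voxels = 10,
                                            max_growth_mm = 3),
                           n_bins = 40L,
                           profile_rois = c("femur_r", "femur_l", "ppj",
                                            "sacrum"),
                           segments = list(acetabular = list(
                             roi = "ppj", range = c(0.7, 1))),
                           suv_threshold = 2.5, test_var_equal = FALSE,
                           p_adjust = "none", seed = 1L) {
  list(spillover = spillover, n_bins = as.integer(n_bins),
       profile_rois = profile_rois, segments = segments,
       suv_threshold = suv_threshold, test_var_equal = test_var_equal,
       p_adjust = p_adjust, seed = as.integer(seed))
}

#' Read a pipeline configuration from YAML
#'
#' Missing fields fall back to [pipelineConfig()] defaults.
#'
#' @param path YAML file.
#' @return Config list.
#' @export
readPipelineConfig <- function(path) {
  user <- yaml::read_yaml(path)
  base <- pipelineConfig()
  utils::modifyList(base, user)
}

#' Run the full quantification pipeline over a cohort
#'
#' For every manifest session: detect and grow the spillover mask, compute
#' the whole-ROI metric panels (with and without the mask for provenance)
#' and the long-axis profiles; then assemble baseline deltas, per-day sex
#' t-test grids, segment-restricted tests, and profile plots into a report
#' directory. Outputs are pure functions of (inputs, config, seed); CSV
#' formatting is fixed so re-runs on identical inputs match byte-for-byte.
#'
#' @param config list from [pipelineConfig()] / [readPipelineConfig()].
#' @param manifest manifest data.frame ([readManifest()]) or a path to a
#'   manifest CSV.
#' @param out_dir report directory (created).
#' @param sessions optional named list of \linkS4class{ScanSession}s keyed
#'   "subject_day", bypassing file I/O (in-memory cohorts).
#' @return Invisibly, list(panels, deltas, tests, segment_tests).
#' @export
runPipeline <- function(config, manifest = NULL, out_dir,
                        sessions = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(sessions)) {
    if (is.character(manifest)) manifest <- readManifest(manifest)
    sessions <- list()
    for (r in seq_len(nrow(manifest))) {
      row <- manifest[r, ]
      sessions[[sprintf("%s_%d", row$subject_id, row$day)]] <-
        tryCatch(loadSession(row), error = function(e)
          stop("session ", row$subject_id, " day ", row$day, ": ",
               conditionMessage(e)))
    }
  }
  spills <- list()
  panels <- list()
  profiles <- stats::setNames(
    vector("list", length(config$profile_rois)), config$profile_rois)
  baseline_axes <- list()
  spill_rows <- list()
  for (key in names(sessions)) {
    ses <- sessions[[key]]
    sp <- NULL
    if (isTRUE(config$spillover$enabled)) {
      pars <- do.call(spilloverParams,
                      config$spillover[setdiff(names(config$spillover),
                                               "enabled")])
      sp <- spilloverMask(ses@pet, ses@labels, pars)
      spills[[key]] <- sp
      spill_rows[[key]] <- data.frame(
        subject_id = ses@subject_id, day = ses@day,
        n_regions = nrow(sp@regions), n_masked = sum(sp@data),
        t(removedFractions(sp)))
    }
    panels[[key]] <- sessionPanels(ses, sp, config$suv_threshold)
    for (roi in config$profile_rois) {
      akey <- paste0(ses@subject_id, "_", roi)
      ref <- baseline_axes[[akey]]
      prof <- projectROI(ses, roi, config$n_bins, sp, reference_axis = ref,
                         threshold = config$suv_threshold)
      if (ses@day == 0L) baseline_axes[[akey]] <- prof@axis
      profiles[[roi]] <- c(profiles[[roi]], list(prof))
      utils::write.csv(
        within(profileMetrics(prof),
               {t_center_mm <- sprintf("%.6g", t_center_mm)
                t_center_norm <- sprintf("%.6g", t_center_norm)}),
        file.path(out_dir, sprintf("profile_%s_%s.csv", key, roi)),
        row.names = FALSE, quote = FALSE)
    }
  }
  panels <- do.call(rbind, c(panels, make.row.names = FALSE))
  utils::write.csv(panels, file.path(out_dir, "panels.csv"),
                   row.names = FALSE, quote = FALSE)
  if (length(spill_rows))
    utils::write.csv(do.call(rbind, c(spill_rows, make.row.names = FALSE)),
                     file.path(out_dir, "spillover.csv"),
                     row.names = FALSE, quote = FALSE)
  deltas <- baselineDelta(panels)
  tests <- cohortReport(deltas, out_dir, adjust = config$p_adjust,
                        profiles = profiles)
  seg_tests <- list()
  days <- sort(setdiff(unique(vapply(sessions, function(s) s@day, 0L)), 0L))
  nf <- length(unique(vapply(sessions, function(s)
    if (s@sex == "female") s@subject_id else NA_character_, "")))
  for (segname in names(config$segments)) {
    seg <- config$segments[[segname]]
    for (d in days) for (m in c("suv_mean", "hu_mean")) {
      res <- tryCatch(
        segmentTTest(unname(sessions), seg$roi, seg$range, d, m,
                     config$n_bins, spills, config$test_var_equal,
                     config$suv_threshold),
        error = function(e) NULL)
      if (!is.null(res)) {
        res$segment <- segname
        seg_tests[[length(seg_tests) + 1L]] <- res
      }
    }
  }
  if (length(seg_tests)) {
    st <- do.call(rbind, seg_tests)
    st$p_value <- sprintf("%.6g", st$p_value)
    st$t_statistic <- sprintf("%.6g", st$t_statistic)
    st$df <- sprintf("%.6g", st$df)
    utils::write.csv(st, file.path(out_dir, "segment_tests.csv"),
                     row.names = FALSE, quote = FALSE)
  }
  yaml::write_yaml(config, file.path(out_dir, "config_resolved.yaml"))
  writeLines(c(sprintf("sessions: %d", length(sessions)),
               sprintf("config_hash: %s",
                       .hashString(yaml::as.yaml(config)))),
             file.path(out_dir, "run_log.txt"))
  invisible(list(panels = panels, deltas = deltas, tests = tests,
                 segment_tests = if (length(seg_tests))
                   do.call(rbind, seg_tests) else NULL))
}

# Tiny stable string hash (FNV-1a) for run provenance.
.hashString <- function(s) {
  b <- utf8ToInt(s)
  h <- 2166136261
  for (x in b) h <- ((bitwXor(as.integer(h %% 2^31), x)) * 16777619) %% 2^32
  sprintf("%08x", as.integer(h %% 2^31))
}
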