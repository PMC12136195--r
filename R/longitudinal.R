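# Baseline-delta tables and female-vs-male tests.
#
# Each subject serves as its own control: every metric is referenced to the
# subject's own day-0 (pre-tumor) value, and sex differences in those
# deltas are tested per (day, ROI, metric) with a two-sided Welch t-test.

.PANEL_METRICS <- c("suv_mean", "suv_median", "suv_q75", "suv_q90",
                    "suv_q95", "suv_max", "suv_std", "frac_suv_gt_thr",
                    "hu_mean", "hu_max", "hu_std", "frac_hu_300_800",
                    "frac_hu_gt_1000")

#' Baseline deltas for a cohort metric table
#'
#' Takes a long or wide metric table over sessions (as produced by
#' [sessionPanels()] row-bound over a cohort) and subtracts each subject's
#' own day-0 value metric-wise. Day-0 rows get delta 0.
#'
#' @param panels data.frame with columns subject_id, sex, day, roi and the
#'   metric columns of [panelForMask()].
#' @param metrics metric column names to unpivot (default: the full panel).
#' @return data.frame with one row per (subject, day, roi, metric):
#'   subject_id, sex, day, roi, metric, value, baseline_value, delta.
#' @export
baselineDelta <- function(panels, metrics = .PANEL_METRICS) {
  metrics <- intersect(metrics, names(panels))
  if (!length(metrics)) stop("no metric columns found")
  if (anyDuplicated(panels[c("subject_id", "day", "roi")]))
    stop("duplicate (subject, day, roi) rows")
  long <- do.call(rbind, lapply(metrics, function(m) {
    data.frame(subject_id = panels$subject_id, sex = panels$sex,
               day = panels$day, roi = panels$roi, metric = m,
               value = panels[[m]])
  }))
  base <- long[long$day == 0, c("subject_id", "roi", "metric", "value")]
  names(base)[4] <- "baseline_value"
  out <- merge(long, base, by = c("subject_id", "roi", "metric"),
               all.x = TRUE, sort = FALSE)
  if (anyNA(out$baseline_value)) {
    bad <- unique(out[is.na(out$baseline_value),
                      c("subject_id", "roi", "metric")])
    stop("missing day-0 baseline for: ",
         paste(unique(bad$subject_id), collapse = ", "))
  }
  out$delta <- out$value - out$baseline_value
  out <- out[order(out$subject_id, out$day, out$roi, out$metric),
             c("subject_id", "sex", "day", "roi", "metric", "value",
               "baseline_value", "delta")]
  rownames(out) <- NULL
  out
}

#' Female-vs-male t-test on baseline deltas
#'
#' Two-sided two-sample t-test comparing female and male deltas at one
#' (day, ROI, metric) cell. Welch's unequal-variance form is the default;
#' the pooled Student form is available via \code{var_equal = TRUE}. When
#' both groups are constant with equal means the test is degenerate and is
#' reported as t = 0, p = 1.
#'
#' @param deltas a [baselineDelta()] table.
#' @param day,roi,metric the cell to test.
#' @param var_equal use the pooled-variance Student form (default FALSE).
#' @return One-row data.frame: day, roi, metric, n_f, n_m, t_statistic, df,
#'   p_value, tail.
#' @export
sexTTest <- function(deltas, day, roi, metric, var_equal = FALSE) {
  sel <- deltas$day == day & deltas$roi == roi & deltas$metric == metric
  f <- deltas$delta[sel & deltas$sex == "female"]
  m <- deltas$delta[sel & deltas$sex == "male"]
  if (length(f) < 2L || length(m) < 2L)
    stop("insufficient group size: need >= 2 females and >= 2 males, got ",
         length(f), "/", length(m))
  if (stats::sd(f) == 0 && stats::sd(m) == 0) {
    if (mean(f) == mean(m)) {
      tt <- list(statistic = 0, parameter = length(f) + length(m) - 2,
                 p.value = 1)
    } else {
      tt <- list(statistic = sign(mean(f) - mean(m)) * Inf,
                 parameter = length(f) + length(m) - 2, p.value = 0)
    }
  } else {
    ht <- stats::t.test(f, m, var.equal = var_equal)
    tt <- list(statistic = unname(ht$statistic),
               parameter = unname(ht$parameter), p.value = ht$p.value)
  }
  data.frame(day = day, roi = roi, metric = metric,
             n_f = length(f), n_m = length(m),
             t_statistic = tt$statistic, df = tt$parameter,
             p_value = tt$p.value, tail = "two-sided")
}

#' Segment-restricted female-vs-male t-test
#'
#' Restricts quantification to an axial segment of a bone (e.g. the
#' acetabular segment of the PPJ), then runs the baseline-delta sex test.
#' For each subject the long axis and bin edges are derived from the
#' subject's own baseline scan (fixed-edges binning), so the segment is
#' anatomically consistent across that subject's timepoints.
#'
#' @param sessions list of \linkS4class{ScanSession}s covering day 0 and the
#'   tested day for every subject.
#' @param roi ROI name(s), e.g. "ppj".
#' @param t_range normalized axial interval, e.g. c(0.7, 1).
#' @param day the post-baseline day to test.
#' @param metric panel metric name, e.g. "hu_mean".
#' @param n_bins slices per bone (default 40).
#' @param spills optional named list of \linkS4class{SpilloverMask}s keyed
#'   by "subject_day".
#' @param var_equal use the pooled Student form.
#' @param threshold SUV exceedance threshold.
#' @return One-row data.frame as [sexTTest()].
#' @export
segmentTTest <- function(sessions, roi, t_range, day, metric, n_bins = 40L,
                         spills = NULL, var_equal = FALSE, threshold = 2.5) {
  days <- vapply(sessions, function(s) s@day, 0L)
  subj <- vapply(sessions, function(s) s@subject_id, "")
  rows <- list()
  for (id in unique(subj)) {
    s0 <- sessions[[which(subj == id & days == 0L)[1]]]
    sd_ <- sessions[[which(subj == id & days == day)[1]]]
    if (is.null(s0) || is.null(sd_))
      stop("subject ", id, " lacks day 0 or day ", day)
    sp0 <- spills[[paste0(id, "_", 0)]]
    spd <- spills[[paste0(id, "_", day)]]
    base_mask <- combineROIs(s0@labels, roi)
    axis0 <- orientAxis(fitLongAxis(base_mask, s0@labels@transform))
    prof0 <- assignSlices(base_mask, axis0, n_bins, s0@labels@transform)
    seg0 <- selectSegment(prof0, t_range, dim(s0@ct@data))
    p0 <- panelForMask(s0@pet, s0@ct, seg0, sp0, threshold)
    axisD <- orientAxis(fitLongAxis(combineROIs(sd_@labels, roi),
                                    sd_@labels@transform), axis0)
    # carry the baseline edges over: same physical span along the bone
    profD <- assignSlices(combineROIs(sd_@labels, roi), axisD, n_bins,
                          sd_@labels@transform, mode = "fixed_edges",
                          edges = prof0@bin_edges)
    segD <- selectSegment(profD, t_range, dim(sd_@ct@data))
    pD <- panelForMask(sd_@pet, sd_@ct, segD, spd, threshold)
    rows[[length(rows) + 1L]] <- data.frame(
      subject_id = id, sex = s0@sex, day = c(0L, day),
      roi = paste(roi, collapse = "+"),
      rbind(p0, pD))
  }
  panels <- do.call(rbind, rows)
  deltas <- baselineDelta(panels, metrics = metric)
  sexTTest(deltas, day, paste(roi, collapse = "+"), metric, var_equal)
}

#' Cohort report: p-value grids and profile summaries
#'
#' Writes per-day p-value grids (ROIs x metrics, one CSV per day), the full
#' delta table, and - when profiles are supplied - mean +/- std profile
#' plots across subjects per ROI/metric. CSV float formatting is fixed so
#' re-running on identical inputs reproduces identical files.
#'
#' @param deltas a [baselineDelta()] table for the whole cohort.
#' @param out_dir output directory (created if needed).
#' @param alpha significance threshold recorded in the grid (default 0.05).
#' @param adjust optional p-value adjustment method (e.g. "BH"); default
#'   "none", matching the presentation of raw p-values.
#' @param profiles optional named list of lists of
#'   \linkS4class{SliceProfile}s (per ROI, across subjects) to plot.
#' @param plot_metrics profile metrics to plot.
#' @return Invisibly, the data.frame of all tests performed.
#' @export
cohortReport <- function(deltas, out_dir, alpha = 0.05, adjust = "none",
                         profiles = NULL,
                         plot_metrics = c("frac_suv_gt_thr", "suv_max",
                                          "suv_mean")) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fmt <- function(x) ifelse(is.na(x), "NA", sprintf("%.6g", x))
  tests <- list()
  days <- sort(setdiff(unique(deltas$day), 0))
  rois <- unique(deltas$roi)
  mets <- unique(deltas$metric)
  for (d in days) {
    grid <- matrix(NA_real_, length(rois), length(mets),
                   dimnames = list(rois, mets))
    for (r in rois) for (m in mets) {
      nf <- sum(deltas$day == d & deltas$roi == r & deltas$metric == m &
                deltas$sex == "female")
      nm <- sum(deltas$day == d & deltas$roi == r & deltas$metric == m &
                deltas$sex == "male")
      if (nf < 2 || nm < 2) next
      res <- sexTTest(deltas, d, r, m)
      grid[r, m] <- res$p_value
      tests[[length(tests) + 1L]] <- res
    }
    if (adjust != "none") {
      adj <- stats::p.adjust(as.vector(grid), method = adjust)
      grid <- matrix(adj, nrow(grid), ncol(grid), dimnames = dimnames(grid))
    }
    df <- data.frame(roi = rownames(grid),
                     apply(grid, 2, fmt, simplify = FALSE),
                     check.names = FALSE)
    utils::write.csv(df, file.path(out_dir, sprintf("pvalues_day%02d.csv", d)),
                     row.names = FALSE, quote = FALSE)
  }
  dl <- deltas
  for (cn in c("value", "baseline_value", "delta")) dl[[cn]] <- fmt(dl[[cn]])
  utils::write.csv(dl, file.path(out_dir, "deltas.csv"),
                   row.names = FALSE, quote = FALSE)
  if (!is.null(profiles)) .plotProfiles(profiles, out_dir, plot_metrics)
  out <- if (length(tests)) do.call(rbind, tests) else
    data.frame(day = integer(), roi = character(), metric = character(),
               n_f = integer(), n_m = integer(), t_statistic = numeric(),
               df = numeric(), p_value = numeric(), tail = character())
  utils::write.csv(
    within(out, {p_value <- fmt(p_value); t_statistic <- fmt(t_statistic)
                 df <- fmt(df)}),
    file.path(out_dir, "tests.csv"), row.names = FALSE, quote = FALSE)
  invisible(out)
}

# Mean +/- std profile plots across subjects, one panel per metric.
.plotProfiles <- function(profiles, out_dir, plot_metrics) {
  for (roi in names(profiles)) {
    plist <- profiles[[roi]]
    if (!length(plist)) next
    f <- file.path(out_dir, sprintf("profile_%s.svg", roi))
    grDevices::svg(f, width = 4 * length(plot_metrics), height = 4)
    graphics::par(mfrow = c(1, length(plot_metrics)), mar = c(4, 4, 2, 1))
    for (m in plot_metrics) {
      tabs <- lapply(plist, function(p) {
        mt <- p@metrics
        mt[!mt$empty, c("t_center_norm", m)]
      })
      xs <- tabs[[1]]$t_center_norm
      ys <- vapply(tabs, function(tb)
        stats::approx(tb$t_center_norm, tb[[m]], xout = xs, rule = 2)$y,
        numeric(length(xs)))
      mu <- rowMeans(ys)
      sdv <- apply(ys, 1, stats::sd)
      graphics::plot(xs, mu, type = "l", lwd = 2, xlab = "relative location",
                     ylab = m, main = roi,
                     ylim = range(c(mu - sdv, mu + sdv), finite = TRUE))
      graphics::polygon(c(xs, rev(xs)), c(mu - sdv, rev(mu + sdv)),
                        col = grDevices::adjustcolor("steelblue", 0.3),
                        border = NA)
      graphics::lines(xs, mu, lwd = 2, col = "steelblue4")
    }
    grDevices::dev.off()
  }
}
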