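# Synthetic digital-mouse PET/CT phantom with per-voxel ground truth.
#
# The phantom paints a simplified pelvis/spine/femur skeleton from analytic
# solids (signed-distance functions) on a world grid centered on the
# anatomy: a curved spinal tube, a sacral cylinder, two iliac-blade
# ellipsoids with acetabular spheres (together the PPJ), and two femurs
# (head sphere + shaft cylinder). CT paints a cortical shell around a
# trabecular core for every bone inside a soft-tissue body; PET is a
# constant background plus joint-adjacent lesion Gaussians whose amplitude
# follows a per-day growth schedule, plus a bladder hotspot whose Gaussian
# tail is the spillover component. The noiseless SUV decomposition
# (background / lesion / spillover) is returned as ground truth, so the
# spillover-removal and projection stages can be validated voxel-by-voxel.
# Repositioning between imaging days is a rigid change of the world
# transform (the animal moves; its anatomy does not).
#
# Anatomy frame: x = left-right (right at +x), y = cranio-caudal (head at
# -y), z = postero-anterior. All lengths in mm.

.PHANTOM_FOV <- c(19.2, 32, 19.2)

.DEFAULT_LESIONS <- data.frame(
  name = c("femur_r_head", "acetab_l", "sacroiliac"),
  bone = c("femur_r", "ppj", "sacrum"),
  x = c(5.0, -2.6, 0), y = c(4.05, 3.8, 0.45), z = c(0.3, 0.3, 0.96),
  sigma = c(0.28, 0.28, 0.28))

.DEFAULT_SCHEDULE <- data.frame(day = c(0L, 11L, 18L, 25L, 32L),
                                amplitude = c(0, 1.5, 4, 5, 6))

#' Phantom specification
#'
#' All defaults together define the package's reference digital mouse:
#' 0.2 mm isotropic grid over a 19.2 x 32 x 19.2 mm field of view, HU
#' levels air -1000 / soft tissue 40 / trabecular 500 / cortical 1200 with
#' 30 HU noise, PET background SUV 0.3 with 0.05 noise, three
#' joint-adjacent lesions (right femoral head, left acetabulum,
#' sacroiliac) growing over imaging days 0/11/18/25/32, and a bladder
#' hotspot (peak SUV 30, 1.5 mm Gaussian decay) anterior-caudal of the
#' pelvis. Sex effects: a female lesion-amplitude multiplier at day 18 and
#' a female acetabular HU decrement at days 25/32.
#'
#' @param sex "female" or "male".
#' @param seed integer subject seed; drives the subject-level amplitude
#'   factor, HU offset, repositioning and noise deterministically.
#' @param spacing isotropic voxel size in mm (default 0.2); the grid covers
#'   the fixed field of view, so 0.4 gives a half-resolution phantom.
#' @param hu_levels named numeric: air, soft, trabecular, cortical.
#' @param hu_noise_sd CT noise sd in HU.
#' @param suv_background,suv_noise_sd PET background level and noise sd.
#' @param lesions data.frame(name, bone, x, y, z, sigma) of lesion centers
#'   (anatomy mm) and Gaussian widths; NULL for none.
#' @param schedule data.frame(day, amplitude): lesion peak SUV per day.
#' @param bladder numeric(5): center x/y/z, peak SUV, decay scale mm;
#'   peak 0 disables excretion.
#' @param sex_effects list(suv_mult_day18, hu_drop, hu_drop_days): female
#'   day-18 lesion multiplier and late acetabular HU decrement.
#' @param subject_sd list(lesion_amp, hu_offset): between-subject
#'   variability (log-normal amplitude factor sd; constant HU offset sd).
#' @param reposition apply a random rigid repositioning on days > 0.
#' @param include_bones subset of bones to paint (default all five).
#' @return A classed list ("PhantomSpec").
#' @export
phantomSpec <- function(sex = "female", seed = 1L, spacing = 0.2,
                        hu_levels = c(air = -1000, soft = 40,
                                      trabecular = 500, cortical = 1200),
                        hu_noise_sd = 30,
                        suv_background = 0.3, suv_noise_sd = 0.05,
                        lesions = .DEFAULT_LESIONS,
                        schedule = .DEFAULT_SCHEDULE,
                        bladder = c(x = 0, y = 4.6, z = 3.4, peak = 30,
                                    decay = 1.5),
                        sex_effects = list(suv_mult_day18 = 1.6,
                                           hu_drop = 180,
                                           hu_drop_days = c(25L, 32L)),
                        subject_sd = list(lesion_amp = 0.15, hu_offset = 10),
                        reposition = TRUE,
                        include_bones = c("spine", "sacrum", "ppj",
                                          "femur_r", "femur_l")) {
  stopifnot(spacing > 0, sex %in% c("female", "male"),
            bladder[["decay"]] > 0,
            hu_levels[["air"]] < hu_levels[["soft"]],
            hu_levels[["soft"]] < hu_levels[["trabecular"]],
            hu_levels[["trabecular"]] < hu_levels[["cortical"]])
  grid_dim <- as.integer(round(.PHANTOM_FOV / spacing))
  structure(list(sex = sex, seed = as.integer(seed), spacing = spacing,
                 grid_dim = grid_dim, hu_levels = hu_levels,
                 hu_noise_sd = hu_noise_sd, suv_background = suv_background,
                 suv_noise_sd = suv_noise_sd, lesions = lesions,
                 schedule = schedule, bladder = bladder,
                 sex_effects = sex_effects, subject_sd = subject_sd,
                 reposition = reposition, include_bones = include_bones),
            class = "PhantomSpec")
}

# Base affine: world = spacing * index - centered, so the grid is symmetric
# about the anatomy origin (mirror pairs of sagittal slices are exact).
.phantomBaseAffine <- function(spec) {
  A <- diag(4)
  A[1:3, 1:3] <- diag(spec$spacing, 3, 3)
  A[1:3, 4] <- -spec$spacing * (spec$grid_dim - 1) / 2
  A
}

.phantomCoords <- function(spec) {
  d <- spec$grid_dim; sp <- spec$spacing
  xv <- sp * (seq_len(d[1]) - 1) - sp * (d[1] - 1) / 2
  yv <- sp * (seq_len(d[2]) - 1) - sp * (d[2] - 1) / 2
  zv <- sp * (seq_len(d[3]) - 1) - sp * (d[3] - 1) / 2
  list(X = array(rep(xv, times = d[2] * d[3]), d),
       Y = array(rep(rep(yv, each = d[1]), times = d[3]), d),
       Z = array(rep(zv, each = d[1] * d[2]), d))
}

.sdSphere <- function(co, c3, r)
  sqrt((co$X - c3[1])^2 + (co$Y - c3[2])^2 + (co$Z - c3[3])^2) - r

.sdCappedCyl <- function(co, p0, p1, r) {
  a <- p1 - p0; L <- sqrt(sum(a^2)); u <- a / L
  wx <- co$X - p0[1]; wy <- co$Y - p0[2]; wz <- co$Z - p0[3]
  t <- wx * u[1] + wy * u[2] + wz * u[3]
  rad2 <- pmax(wx^2 + wy^2 + wz^2 - t^2, 0)
  pmax(sqrt(rad2) - r, pmax(-t, t - L))
}

.sdEllipsoid <- function(co, c3, s) {
  (sqrt(((co$X - c3[1]) / s[1])^2 + ((co$Y - c3[2]) / s[2])^2 +
        ((co$Z - c3[3]) / s[3])^2) - 1) * min(s)
}

# Curved spinal tube: centerline x = 0, z = 0.4 - 0.012 (y + 2)^2 for
# y in [-15.2, -2], radius 1.1.
.sdSpine <- function(co) {
  yc <- pmin(pmax(co$Y, -15.2), -2)
  zc <- 0.4 - 0.012 * (yc + 2)^2
  radial <- sqrt(co$X^2 + (co$Z - zc)^2) - 1.1
  axial <- pmax(-15.2 - co$Y, co$Y - (-2))
  pmax(radial, axial)
}

.FEMUR_DIR <- c(0.2208, 0.9735, 0.0602) / sqrt(sum(c(0.2208, 0.9735, 0.0602)^2))
.FEMUR_HEAD_R <- c(5.0, 4.05, 0.3)
.ACETAB_R <- c(2.6, 3.8, 0.3)

# Pelvis proportions are chosen so the PPJ's first principal component runs
# cranio-caudally (iliac blades elongated along y, acetabula at the caudal
# end, landing at ~0.79-1.0 of the normalized long axis).
.phantomBoneSDFs <- function(co) {
  u <- .FEMUR_DIR
  headR <- .FEMUR_HEAD_R; headL <- headR * c(-1, 1, 1)
  acR <- .ACETAB_R; acL <- acR * c(-1, 1, 1)
  uL <- u * c(-1, 1, 1)
  list(
    spine = .sdSpine(co),
    sacrum = .sdCappedCyl(co, c(0, -2, 0.4), c(0, 1.5, 1.2), 1.3),
    ppj = pmin(
      .sdEllipsoid(co, c(1.8, -1.3, -0.5), c(0.9, 4.5, 1.6)),
      .sdEllipsoid(co, c(-1.8, -1.3, -0.5), c(0.9, 4.5, 1.6)),
      .sdSphere(co, acR, 1.1),
      .sdSphere(co, acL, 1.1)),
    femur_r = pmin(.sdSphere(co, headR, 1.1),
                   .sdCappedCyl(co, headR, headR + 6.5 * u, 0.9)),
    femur_l = pmin(.sdSphere(co, headL, 1.1),
                   .sdCappedCyl(co, headL, headL + 6.5 * uL, 0.9)))
}

# Acetabular region: the two acetabular spheres, slightly dilated - the
# site of the simulated female late-stage bone-density loss.
.acetabMask <- function(co) {
  .sdSphere(co, .ACETAB_R, 1.6) <= 0 |
    .sdSphere(co, .ACETAB_R * c(-1, 1, 1), 1.6) <= 0
}

#' Precompute the phantom anatomy on its grid
#'
#' Paints the label map, the noiseless CT (cortical shell 0.25 mm around a
#' trabecular core, soft-tissue body, air outside) and the unit-amplitude
#' lesion and spillover bases. Cache this when generating many sessions of
#' the same geometry - sessions differ only by amplitudes, sex effects,
#' transform and noise.
#'
#' @param spec a [phantomSpec()].
#' @return An opaque anatomy list consumed by [generateSession()].
#' @export
buildAnatomy <- function(spec) {
  co <- .phantomCoords(spec)
  d <- spec$grid_dim
  shell <- 0.25
  sdfs <- .phantomBoneSDFs(co)[spec$include_bones]
  hu <- spec$hu_levels
  body <- ((co$X / 9.0)^4 + (co$Y / 15.4)^4 + (co$Z / 9.0)^4) < 1
  ct <- array(hu[["air"]], d)
  ct[body] <- hu[["soft"]]
  labels <- array(0L, d)
  lab <- roiLabels()
  for (bone in names(sdfs)) {
    sd_ <- sdfs[[bone]]
    inside <- sd_ <= 0
    ct[inside & sd_ > -shell] <- hu[["cortical"]]
    ct[sd_ <= -shell] <- hu[["trabecular"]]
    paint <- inside & labels == 0L
    labels[paint] <- lab[[bone]]
  }
  lesion_basis <- list()
  if (!is.null(spec$lesions) && nrow(spec$lesions)) {
    for (li in seq_len(nrow(spec$lesions))) {
      L <- spec$lesions[li, ]
      r2 <- (co$X - L$x)^2 + (co$Y - L$y)^2 + (co$Z - L$z)^2
      sel <- which(r2 < (4.5 * L$sigma)^2)
      lesion_basis[[li]] <- list(idx = sel,
                                 val = exp(-r2[sel] / (2 * L$sigma^2)))
    }
  }
  spill <- array(0, d)
  bl <- spec$bladder
  if (bl[["peak"]] > 0) {
    r2 <- (co$X - bl[["x"]])^2 + (co$Y - bl[["y"]])^2 + (co$Z - bl[["z"]])^2
    sel <- r2 < (6.5 * bl[["decay"]])^2
    spill[sel] <- bl[["peak"]] * exp(-r2[sel] / (2 * bl[["decay"]]^2))
  }
  list(labels = labels, ct_base = ct, lesion_basis = lesion_basis,
       spill = spill, acetab = .acetabMask(co),
       base_affine = .phantomBaseAffine(spec),
       fingerprint = .anatomyFingerprint(spec))
}

# Geometry-determining spec fields; a cached anatomy may only be reused by
# specs that agree on all of them.
.anatomyFingerprint <- function(spec) {
  paste(utils::capture.output(str(spec[c("spacing", "grid_dim", "hu_levels",
                                         "lesions", "bladder",
                                         "include_bones")],
                                  digits.d = 12)), collapse = "\n")
}

# Random small rigid transform (rotations within +/- 8 degrees, translation
# within +/- 1 mm), drawn from the current RNG state.
.randomRigid <- function(max_angle_deg = 8, max_shift_mm = 1) {
  ang <- stats::runif(3, -max_angle_deg, max_angle_deg) * pi / 180
  cx <- cos(ang[1]); sx <- sin(ang[1])
  cy <- cos(ang[2]); sy <- sin(ang[2])
  cz <- cos(ang[3]); sz <- sin(ang[3])
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
  out <- diag(4)
  out[1:3, 1:3] <- Rz %*% Ry %*% Rx
  out[1:3, 4] <- stats::runif(3, -max_shift_mm, max_shift_mm)
  out
}

# Lesion amplitude on a given day, including the female day-18 multiplier.
.lesionAmplitude <- function(spec, day) {
  row <- spec$schedule[spec$schedule$day == day, ]
  if (!nrow(row)) stop("day ", day, " not in the phantom schedule")
  amp <- row$amplitude[1]
  if (spec$sex == "female" && day == 18L && amp > 0)
    amp <- amp * spec$sex_effects$suv_mult_day18
  amp
}

#' Generate one phantom imaging session
#'
#' @param spec a [phantomSpec()].
#' @param day imaging day; must appear in the spec's schedule.
#' @param anatomy optional cached [buildAnatomy()] result for this spec's
#'   geometry (subject-independent), to amortize painting cost.
#' @return list(ct, pet, labels, truth): CT/PET as
#'   \linkS4class{ImageVolume}s, labels as \linkS4class{LabelMap}, and
#'   truth carrying the noiseless SUV decomposition (background, lesion,
#'   spillover arrays summing to the noiseless total), the lesion table
#'   with world-mm centers, the applied rigid transform and the acetabular
#'   effect mask. Identical (spec, day) input reproduces bitwise-identical
#'   output.
#' @export
generateSession <- function(spec, day, anatomy = NULL) {
  if (is.null(anatomy)) anatomy <- buildAnatomy(spec)
  else if (!identical(anatomy$fingerprint, .anatomyFingerprint(spec)))
    stop("the supplied anatomy was built for a different phantom geometry")
  d <- spec$grid_dim
  # subject-level draws (constant across this subject's days)
  set.seed(.deriveSeed(spec$seed, 1L))
  amp_factor <- exp(stats::rnorm(1, 0, spec$subject_sd$lesion_amp))
  hu_offset <- stats::rnorm(1, 0, spec$subject_sd$hu_offset)
  # per-day rigid repositioning (day 0 = reference position)
  set.seed(.deriveSeed(spec$seed, 100L + day))
  rigid <- if (spec$reposition && day > 0L) .randomRigid() else diag(4)
  transform <- rigid %*% anatomy$base_affine
  amp <- .lesionAmplitude(spec, day) * amp_factor
  lesion <- array(0, d)
  for (lb in anatomy$lesion_basis) lesion[lb$idx] <- lesion[lb$idx] + amp * lb$val
  total_clean <- spec$suv_background + lesion + anatomy$spill
  ct_clean <- anatomy$ct_base + hu_offset
  hu_dropped <- FALSE
  if (spec$sex == "female" && day %in% spec$sex_effects$hu_drop_days) {
    ct_clean[anatomy$acetab] <- ct_clean[anatomy$acetab] - spec$sex_effects$hu_drop
    hu_dropped <- TRUE
  }
  set.seed(.deriveSeed(spec$seed, 1000L + day))
  pet_data <- total_clean
  if (spec$suv_noise_sd > 0)
    pet_data <- pet_data + stats::rnorm(prod(d), 0, spec$suv_noise_sd)
  ct_data <- ct_clean
  if (spec$hu_noise_sd > 0)
    ct_data <- ct_data + stats::rnorm(prod(d), 0, spec$hu_noise_sd)
  pet <- ImageVolume(array(pmax(pet_data, 0), d), transform = transform,
                     modality = "SUV")
  ct <- ImageVolume(array(pmax(ct_data, -1024), d), transform = transform,
                    modality = "HU")
  labels <- LabelMap(anatomy$labels, transform = transform)
  lesion_table <- NULL
  if (!is.null(spec$lesions) && nrow(spec$lesions)) {
    ctr <- as.matrix(spec$lesions[, c("x", "y", "z")])
    ctr_w <- t(rigid[1:3, 1:3] %*% t(ctr)) +
      matrix(rigid[1:3, 4], nrow(ctr), 3, byrow = TRUE)
    lesion_table <- data.frame(spec$lesions,
                               wx = ctr_w[, 1], wy = ctr_w[, 2],
                               wz = ctr_w[, 3], amplitude = amp)
  }
  truth <- list(background = spec$suv_background, lesion = lesion,
                spill = anatomy$spill, total_noiseless = total_clean,
                lesion_table = lesion_table, rigid = rigid,
                acetab_mask = anatomy$acetab, hu_drop_applied = hu_dropped,
                amp_factor = amp_factor, hu_offset = hu_offset)
  list(ct = ct, pet = pet, labels = labels, truth = truth)
}

#' Ground-truth spillover-dominance mask
#'
#' TRUE where the spillover component exceeds \code{dominance} of the
#' noiseless total SUV - the reference against which the spillover-removal
#' algorithm's mask is scored.
#'
#' @param truth the truth element of a [generateSession()] result.
#' @param dominance fraction in (0, 1).
#' @return Logical 3D array.
#' @export
spilloverTruthMask <- function(truth, dominance) {
  stopifnot(dominance > 0, dominance < 1)
  truth$spill / truth$total_noiseless > dominance
}

#' Build the specs of a two-sex cohort
#'
#' @param n_female,n_male subjects per group.
#' @param seed master seed; subject seeds are derived from it.
#' @param ... forwarded to [phantomSpec()] (e.g. spacing, bladder,
#'   sex_effects).
#' @return Named list of [phantomSpec()]s keyed by subject id (F1.., M1..).
#' @export
cohortSpecs <- function(n_female = 4L, n_male = 4L, seed = 1L, ...) {
  specs <- list()
  for (i in seq_len(n_female))
    specs[[paste0("F", i)]] <- phantomSpec(sex = "female",
                                           seed = .deriveSeed(seed, i), ...)
  for (i in seq_len(n_male))
    specs[[paste0("M", i)]] <- phantomSpec(sex = "male",
                                           seed = .deriveSeed(seed, 1000L + i), ...)
  specs
}

#' Generate a phantom cohort on disk
#'
#' Writes per-session NIfTI triplets (PET, CT, labels), a manifest CSV in
#' the [readManifest()] schema, and a ground-truth JSON (lesion centers and
#' amplitudes, applied rigid transforms). Optionally writes the noiseless
#' lesion/spillover component volumes per session.
#'
#' @param specs named list from [cohortSpecs()].
#' @param days integer vector of imaging days (must include 0).
#' @param out_dir output directory.
#' @param write_components also write decomposition NIfTIs (default FALSE).
#' @return The manifest data.frame, invisibly.
#' @export
generateCohort <- function(specs, days, out_dir, write_components = FALSE) {
  if (!length(specs) || !length(days)) stop("empty cohort specification")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  anatomy <- buildAnatomy(specs[[1]])
  rows <- list()
  truths <- list()
  for (id in names(specs)) {
    spec <- specs[[id]]
    for (day in days) {
      ses <- generateSession(spec, day, anatomy)
      stub <- sprintf("%s_day%02d", id, day)
      pp <- file.path(out_dir, paste0(stub, "_pet.nii.gz"))
      cp <- file.path(out_dir, paste0(stub, "_ct.nii.gz"))
      lp <- file.path(out_dir, paste0(stub, "_labels.nii.gz"))
      writeVolume(ses$pet, pp)
      writeVolume(ses$ct, cp)
      writeLabelMap(ses$labels, lp)
      if (write_components) {
        writeVolume(ImageVolume(ses$truth$lesion,
                                transform = ses$pet@transform,
                                modality = "SUV"),
                    file.path(out_dir, paste0(stub, "_lesion.nii.gz")))
        writeVolume(ImageVolume(ses$truth$spill,
                                transform = ses$pet@transform,
                                modality = "SUV"),
                    file.path(out_dir, paste0(stub, "_spill.nii.gz")))
      }
      rows[[stub]] <- data.frame(subject_id = id, sex = spec$sex, day = day,
                                 pet_path = pp, ct_path = cp, labels_path = lp)
      truths[[stub]] <- list(
        rigid = ses$truth$rigid,
        lesions = ses$truth$lesion_table,
        hu_drop_applied = ses$truth$hu_drop_applied)
    }
  }
  man <- do.call(rbind, rows)
  rownames(man) <- NULL
  # manifest paths are relative to the manifest's own directory
  man_rel <- man
  for (col in c("pet_path", "ct_path", "labels_path"))
    man_rel[[col]] <- basename(man_rel[[col]])
  utils::write.csv(man_rel, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  jsonlite::write_json(truths, file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(man)
}

#' Generate all sessions of a cohort in memory
#'
#' Convenience for tests and simulation studies: no disk I/O, anatomy
#' painted once and shared.
#'
#' @param specs named list from [cohortSpecs()].
#' @param days integer vector of imaging days.
#' @param anatomy optional precomputed [buildAnatomy()].
#' @return Named list of [generateSession()] results keyed by
#'   "subject_day".
#' @export
generateCohortSessions <- function(specs, days, anatomy = NULL) {
  if (is.null(anatomy)) anatomy <- buildAnatomy(specs[[1]])
  out <- list()
  for (id in names(specs)) for (day in days)
    out[[sprintf("%s_%d", id, day)]] <-
      generateSession(specs[[id]], day, anatomy)
  out
}
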