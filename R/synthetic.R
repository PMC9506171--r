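# Synthetic lumbosacral instrumentation cohorts. The generator emulates the
# statistical structure the accuracy analysis assumes -- a per-case
# planning-to-control frame offset, per-screw execution error (isotropic
# head translation plus half-normal axis tilt about a random perpendicular
# axis), reference-screw patient registration with fiducial localization
# noise, per-vertebra verification landmarks, and pedicle corridors -- with
# ground truth retained so every downstream estimate can be checked against
# what was injected. Anatomy is a simplified stacked-vertebra model (33 mm
# level spacing, convergent pedicle trajectories parallel to the endplate);
# it reproduces error magnitudes and cohort composition, not patient shape.

# Default cohort composition: 27 cases, screw-level spinal-level mix and
# construct-length mix as observed in routine lumbosacral CT-navigated
# practice (L1 1.4%, L2 5.7%, L3 17.1%, L4 28.6%, L5 31.4%, S1 15.8%;
# constructs of 1-4 segments at 44.4/37.0/11.1/7.5%).
LEVEL_MIX_DEFAULT <- c(L1 = 2, L2 = 8, L3 = 24, L4 = 40, L5 = 44, S1 = 22) / 140
CONSTRUCT_MIX_DEFAULT <- c(`1` = 12, `2` = 10, `3` = 3, `4` = 2) / 27
# Caudal-most-vertebra sampling weights, jointly calibrated with the
# construct-length mix so that simulated per-level screw frequencies
# reproduce LEVEL_MIX_DEFAULT.
CAUDAL_MIX_DEFAULT <- c(L4 = 0.08, L5 = 0.48, S1 = 0.44)
DIAGNOSIS_MIX_DEFAULT <- c(
  "degenerative spondylolisthesis grade 1" = 15,
  "degenerative spondylolisthesis grade 2" = 1,
  "spondylosis/stenosis" = 9,
  "spondylodiscitis" = 2
) / 27

# Per-level implant and corridor defaults (mm / degrees). Corridor semi-axes
# are plausible literature-style pedicle dimensions (transverse width grows
# L1 -> L5 and is largest at S1); they are configurable, not measurements.
SCREW_LENGTH_DEFAULT <- c(L1 = 45, L2 = 45, L3 = 45, L4 = 45, L5 = 50, S1 = 40)
SCREW_DIAMETER_DEFAULT <- c(L1 = 5.5, L2 = 6.0, L3 = 6.5, L4 = 6.5, L5 = 7.0, S1 = 7.0)
CORRIDOR_TRANSVERSE_DEFAULT <- c(L1 = 3.6, L2 = 4.0, L3 = 4.6, L4 = 5.5, L5 = 7.0, S1 = 8.0)
CORRIDOR_SAGITTAL_DEFAULT <- c(L1 = 7.5, L2 = 7.0, L3 = 7.0, L4 = 6.8, L5 = 6.5, S1 = 8.0)
CONVERGENCE_DEG_DEFAULT <- c(L1 = 5, L2 = 8, L3 = 10, L4 = 12, L5 = 15, S1 = 18)

# Error-model calibration constants (documented, not re-fit at run time):
# - sigma_head_mm = 3.26: isotropic execution noise of the head point; the
#   norm of a 3D isotropic Gaussian is chi(3)-distributed with mean
#   2*sqrt(2/pi)*sigma, so 3.26 mm yields a mean head deviation of 5.20 mm.
# - sigma_angle_deg per level: axis tilt magnitudes are half-normal with
#   mean sigma*sqrt(2/pi); per-level sigmas are benchmark per-level mean
#   angular deviations (5.5/4.8/5.9/5.3/6.4/9.3 degrees for L1-S1, S1
#   deliberately largest) divided by sqrt(2/pi) = 0.79788.
# - sigma_fle_mm = 0.55: fiducial localization noise of the reference-screw
#   registration, calibrated by simulation so the mean per-case target
#   registration error at the screw heads is ~0.87 mm.
SIGMA_HEAD_DEFAULT <- 3.26
SIGMA_ANGLE_DEFAULT <- c(L1 = 5.5, L2 = 4.8, L3 = 5.9, L4 = 5.3, L5 = 6.4,
                         S1 = 9.3) / sqrt(2 / pi)
SIGMA_FLE_DEFAULT <- 0.55

#' @noRd
level_z <- function(level_idx) 33 * (6 - level_idx)

#' Simulation configuration for a synthetic instrumentation cohort
#'
#' All defaults are the calibrated study conditions (see the package
#' vignette): a 27-case lumbosacral cohort whose long-run mean head
#' deviation, angular deviation and navigation registration error sit at
#' 5.2 mm, 6.3 degrees and 0.87 mm respectively.
#'
#' @param n_cases Number of cases.
#' @param seed Integer seed; cohorts are bit-identical given the seed.
#' @param level_mix Target per-screw level proportions (named, L1-S1, sums
#'   to 1). Kept as the reference composition; constructs are placed via
#'   `caudal_mix`.
#' @param construct_length_mix Probabilities of 1-4 instrumented segments.
#' @param caudal_mix Sampling weights of the caudal-most instrumented
#'   vertebra (jointly calibrated with `construct_length_mix` to reproduce
#'   `level_mix`).
#' @param screw_length_mm,screw_diameter_mm Named per-level implant defaults.
#' @param corridor_transverse_mm,corridor_sagittal_mm Named per-level
#'   corridor semi-axes.
#' @param corridor_extent_mm Pedicle segment `(start, end)` along the screw
#'   axis from the entry point, mm.
#' @param convergence_deg Named per-level pedicle convergence angles.
#' @param sigma_fle_mm Fiducial localization noise of the reference-screw
#'   patient registration (per axis, mm).
#' @param sigma_coreg_mm Localization noise of the per-vertebra
#'   co-registration verification landmarks (per axis, mm).
#' @param sigma_head_mm Isotropic execution noise of the screw head (per
#'   axis, mm).
#' @param sigma_angle_deg Half-normal scale of the axis tilt, degrees;
#'   scalar or named per level.
#' @param sigma_frame_rot_deg,sigma_frame_trans_mm Scale of the sampled
#'   planning-to-control frame offset (half-normal rotation angle about a
#'   random axis; isotropic translation).
#' @param per_level_shift_mm Magnitude of a cranio-caudal non-rigid shift
#'   injected at the cranial-most instrumented level of `n_shift_cases`
#'   cases, breaking rigid co-registration there (0 = none).
#' @param n_shift_cases Number of cases receiving the shift.
#' @param diagnosis_mix Named diagnosis probabilities.
#' @param age_mean,age_sd,weight_mean,weight_sd,height_mean,height_sd
#'   Covariate model parameters.
#' @return A `simulation_config` object.
#' @export
simulation_config <- function(n_cases = 27L,
                              seed = 1L,
                              level_mix = LEVEL_MIX_DEFAULT,
                              construct_length_mix = CONSTRUCT_MIX_DEFAULT,
                              caudal_mix = CAUDAL_MIX_DEFAULT,
                              screw_length_mm = SCREW_LENGTH_DEFAULT,
                              screw_diameter_mm = SCREW_DIAMETER_DEFAULT,
                              corridor_transverse_mm = CORRIDOR_TRANSVERSE_DEFAULT,
                              corridor_sagittal_mm = CORRIDOR_SAGITTAL_DEFAULT,
                              corridor_extent_mm = c(8, 28),
                              convergence_deg = CONVERGENCE_DEG_DEFAULT,
                              sigma_fle_mm = SIGMA_FLE_DEFAULT,
                              sigma_coreg_mm = 0.3,
                              sigma_head_mm = SIGMA_HEAD_DEFAULT,
                              sigma_angle_deg = SIGMA_ANGLE_DEFAULT,
                              sigma_frame_rot_deg = 2,
                              sigma_frame_trans_mm = 10,
                              per_level_shift_mm = 0,
                              n_shift_cases = 0L,
                              diagnosis_mix = DIAGNOSIS_MIX_DEFAULT,
                              age_mean = 68, age_sd = 8,
                              weight_mean = 86, weight_sd = 14,
                              height_mean = 170, height_sd = 10) {
  if (length(sigma_angle_deg) == 1L) {
    sigma_angle_deg <- stats::setNames(rep(sigma_angle_deg, 6), SPINAL_LEVELS)
  }
  cfg <- list(
    n_cases = as.integer(n_cases), seed = as.integer(seed),
    level_mix = level_mix, construct_length_mix = construct_length_mix,
    caudal_mix = caudal_mix,
    screw_length_mm = screw_length_mm, screw_diameter_mm = screw_diameter_mm,
    corridor_transverse_mm = corridor_transverse_mm,
    corridor_sagittal_mm = corridor_sagittal_mm,
    corridor_extent_mm = corridor_extent_mm,
    convergence_deg = convergence_deg,
    sigma_fle_mm = sigma_fle_mm, sigma_coreg_mm = sigma_coreg_mm,
    sigma_head_mm = sigma_head_mm, sigma_angle_deg = sigma_angle_deg,
    sigma_frame_rot_deg = sigma_frame_rot_deg,
    sigma_frame_trans_mm = sigma_frame_trans_mm,
    per_level_shift_mm = per_level_shift_mm,
    n_shift_cases = as.integer(n_shift_cases),
    diagnosis_mix = diagnosis_mix,
    age_mean = age_mean, age_sd = age_sd,
    weight_mean = weight_mean, weight_sd = weight_sd,
    height_mean = height_mean, height_sd = height_sd
  )
  sig <- c(cfg$sigma_fle_mm, cfg$sigma_coreg_mm, cfg$sigma_head_mm,
           cfg$sigma_angle_deg, cfg$sigma_frame_rot_deg,
           cfg$sigma_frame_trans_mm, cfg$per_level_shift_mm)
  if (any(sig < 0) || any(!is.finite(sig))) {
    stop_navscrew("all noise scales must be finite and non-negative",
                  "navscrew_config_error")
  }
  for (mx in list(cfg$level_mix, cfg$construct_length_mix, cfg$caudal_mix,
                  cfg$diagnosis_mix)) {
    if (any(mx < 0) || abs(sum(mx) - 1) > 1e-6) {
      stop_navscrew("mix probabilities must be non-negative and sum to 1",
                    "navscrew_config_error")
    }
  }
  if (cfg$n_cases < 1L) stop_navscrew("n_cases must be >= 1", "navscrew_config_error")
  if (cfg$n_shift_cases > cfg$n_cases) {
    stop_navscrew("n_shift_cases cannot exceed n_cases", "navscrew_config_error")
  }
  for (nm in c("level_mix", "screw_length_mm", "screw_diameter_mm",
               "corridor_transverse_mm", "corridor_sagittal_mm",
               "convergence_deg", "sigma_angle_deg")) {
    if (!all(SPINAL_LEVELS %in% names(cfg[[nm]]))) {
      stop_navscrew(sprintf("`%s` must be named for all levels L1-S1", nm),
                    "navscrew_config_error")
    }
    cfg[[nm]] <- cfg[[nm]][SPINAL_LEVELS]  # canonical order for index lookup
  }
  structure(cfg, class = "simulation_config")
}

#' Calibrated study configuration
#'
#' Returns the [simulation_config()] whose defaults reproduce, in the long
#' run, the benchmark accuracy magnitudes of a routine CT-navigated
#' lumbosacral cohort: mean head deviation 5.2 mm, mean angular deviation
#' 6.3 degrees (largest at S1), mean navigation registration error 0.87 mm.
#' All calibration constants are documented in the source and are not re-fit
#' at run time.
#'
#' @param n_cases Number of cases (default 27).
#' @param seed Integer seed.
#' @return A `simulation_config`.
#' @export
calibrated_config <- function(n_cases = 27L, seed = 1L) {
  simulation_config(n_cases = n_cases, seed = seed)
}

#' @export
print.simulation_config <- function(x, ...) {
  cat(sprintf("<simulation_config: %d cases, seed %d>\n", x$n_cases, x$seed))
  cat(sprintf("  sigma_head %.2f mm; sigma_angle %s deg; sigma_fle %.2f mm\n",
              x$sigma_head_mm,
              paste(round(x$sigma_angle_deg, 1), collapse = "/"),
              x$sigma_fle_mm))
  if (x$n_shift_cases > 0) {
    cat(sprintf("  non-rigid shift: %.1f mm in %d case(s)\n",
                x$per_level_shift_mm, x$n_shift_cases))
  }
  invisible(x)
}

#' @noRd
rnorm3 <- function(n, sd) matrix(stats::rnorm(3 * n, 0, sd), n, 3)

#' @noRd
random_unit_rows <- function(n) {
  m <- matrix(stats::rnorm(3 * n), n, 3)
  m / sqrt(rowSums(m^2))
}

#' @noRd
cross_rows <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

#' Simulate a synthetic instrumentation cohort
#'
#' Deterministic given `cfg$seed`. For each case: a construct (caudal
#' vertebra + length sampled from the configured mixes), planned screws
#' following the convergent pedicle anatomy parallel to the superior
#' endplate, pedicle corridors centred on the plans (so every planned screw
#' is grade A by construction), a sampled rigid planning-to-control frame
#' offset, final screws with isotropic head noise and half-normal axis tilt
#' expressed in the control frame, reference-screw fiducial pairs with
#' localization noise, per-vertebra verification landmarks, and covariates.
#' Ground truth (true transform, per-screw perturbations, true registration
#' error) is retained for recovery tests.
#'
#' @param cfg A [simulation_config()].
#' @return A `synthetic_cohort`: list with `config`, `screws` (screw table,
#'   planned rows in frame "navCT", final rows in "controlCT"), `corridors`
#'   (corridor table, "navCT"), `landmarks` (sets "coreg",
#'   "patient_fiducial", "tre_target"), `covariates`, and `ground_truth`
#'   (`cases` data.frame, per-case `transforms`, `screws` truth table).
#' @export
simulate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  set.seed(cfg$seed)
  nc <- cfg$n_cases
  case_id <- sprintf("C%04d", seq_len(nc))

  # construct composition
  nseg <- sample(as.integer(names(cfg$construct_length_mix)), nc,
                 replace = TRUE, prob = cfg$construct_length_mix)
  caudal <- sample(match(names(cfg$caudal_mix), SPINAL_LEVELS), nc,
                   replace = TRUE, prob = cfg$caudal_mix)
  nseg <- pmin(nseg, caudal - 1L)

  # true planning-to-control frame offset per case
  k <- random_unit_rows(nc)
  ang <- abs(stats::rnorm(nc, 0, cfg$sigma_frame_rot_deg)) * pi / 180
  cth <- cos(ang); sth <- sin(ang); om <- 1 - cth
  R <- cbind(
    r11 = cth + k[, 1]^2 * om, r12 = k[, 1] * k[, 2] * om - k[, 3] * sth,
    r13 = k[, 1] * k[, 3] * om + k[, 2] * sth,
    r21 = k[, 2] * k[, 1] * om + k[, 3] * sth, r22 = cth + k[, 2]^2 * om,
    r23 = k[, 2] * k[, 3] * om - k[, 1] * sth,
    r31 = k[, 3] * k[, 1] * om - k[, 2] * sth,
    r32 = k[, 3] * k[, 2] * om + k[, 1] * sth, r33 = cth + k[, 3]^2 * om
  )
  Tt <- rnorm3(nc, cfg$sigma_frame_trans_mm)

  # non-rigid shift (cranial-most instrumented level of selected cases)
  shift_case <- rep(FALSE, nc)
  if (cfg$n_shift_cases > 0L && cfg$per_level_shift_mm > 0) {
    shift_case[sample(nc, cfg$n_shift_cases)] <- TRUE
  }
  cranial_idx <- caudal - nseg

  to_control <- function(ci, m) {
    # apply the per-case frame transform, vectorized over rows via indexing
    cbind(R[ci, "r11"] * m[, 1] + R[ci, "r12"] * m[, 2] + R[ci, "r13"] * m[, 3],
          R[ci, "r21"] * m[, 1] + R[ci, "r22"] * m[, 2] + R[ci, "r23"] * m[, 3],
          R[ci, "r31"] * m[, 1] + R[ci, "r32"] * m[, 2] + R[ci, "r33"] * m[, 3]) +
      Tt[ci, , drop = FALSE]
  }

  # ---- screws ---------------------------------------------------------------
  n_vert <- nseg + 1L
  vert_case <- rep(seq_len(nc), times = n_vert)
  vert_level <- unlist(Map(function(c0, n) (c0 - n):c0, caudal, nseg),
                       use.names = FALSE)
  ns <- 2L * length(vert_level)
  sci <- rep(vert_case, each = 2L)            # case index per screw
  sli <- rep(vert_level, each = 2L)           # level index per screw
  side <- rep(c("left", "right"), length(vert_level))
  ssign <- ifelse(side == "left", 1, -1)

  lev <- SPINAL_LEVELS[sli]
  conv <- cfg$convergence_deg[sli] * pi / 180
  len <- unname(cfg$screw_length_mm[sli])
  dia <- unname(cfg$screw_diameter_mm[sli])
  head_p <- cbind(15 * ssign, 40, level_z(sli))
  dir_p <- cbind(-ssign * sin(conv), -cos(conv), 0)
  tip_p <- head_p + len * dir_p

  # execution error
  dh <- rnorm3(ns, cfg$sigma_head_mm)
  tilt <- abs(stats::rnorm(ns, 0, unname(cfg$sigma_angle_deg[sli]))) * pi / 180
  perp <- random_unit_rows(ns)
  perp <- perp - rowSums(perp * dir_p) * dir_p
  perp <- perp / sqrt(rowSums(perp^2))
  dir_f <- dir_p * cos(tilt) + cross_rows(perp, dir_p) * sin(tilt)

  shiftv <- cbind(0, 0, ifelse(shift_case[sci] & sli == cranial_idx[sci],
                               cfg$per_level_shift_mm, 0))
  head_f_nav <- head_p + dh + shiftv
  tip_f_nav <- head_f_nav + len * dir_f
  head_f <- to_control(sci, head_f_nav)
  tip_f <- to_control(sci, tip_f_nav)

  screw_id <- paste(lev, side, sep = "_")
  planned <- data.frame(
    case_id = case_id[sci], screw_id = screw_id, level = lev, side = side,
    role = "planned",
    head_x = head_p[, 1], head_y = head_p[, 2], head_z = head_p[, 3],
    tip_x = tip_p[, 1], tip_y = tip_p[, 2], tip_z = tip_p[, 3],
    diameter_mm = dia, length_mm = len, frame = "navCT",
    stringsAsFactors = FALSE
  )
  final <- planned
  final$role <- "final"
  final[, c("head_x", "head_y", "head_z")] <- head_f
  final[, c("tip_x", "tip_y", "tip_z")] <- tip_f
  final$frame <- "controlCT"
  screws <- rbind(planned, final)
  rownames(screws) <- NULL

  corridors <- data.frame(
    case_id = case_id[sci], level = lev, side = side,
    axis_x = head_p[, 1], axis_y = head_p[, 2], axis_z = head_p[, 3],
    dir_x = dir_p[, 1], dir_y = dir_p[, 2], dir_z = dir_p[, 3],
    ref_x = 0, ref_y = 0, ref_z = 1,
    semi_transverse_mm = unname(cfg$corridor_transverse_mm[sli]),
    semi_sagittal_mm = unname(cfg$corridor_sagittal_mm[sli]),
    extent_start_mm = cfg$corridor_extent_mm[1],
    extent_end_mm = cfg$corridor_extent_mm[2],
    frame = "navCT", stringsAsFactors = FALSE
  )

  # ---- landmarks ------------------------------------------------------------
  # co-registration verification landmarks: 8 vertebral-body corner points
  corner <- as.matrix(expand.grid(x = c(-20, 20), y = c(-15, 15), z = c(-12, 12)))
  nv <- length(vert_level)
  lci <- rep(vert_case, each = 8L)
  lli <- rep(vert_level, each = 8L)
  ctr <- cbind(0, 0, level_z(lli))
  true_lm <- ctr + corner[rep(seq_len(8L), nv), , drop = FALSE]
  lm_shift <- cbind(0, 0, ifelse(shift_case[lci] & lli == cranial_idx[lci],
                                 cfg$per_level_shift_mm, 0))
  coreg_src <- true_lm + rnorm3(nrow(true_lm), cfg$sigma_coreg_mm)
  coreg_dst <- to_control(lci, true_lm + lm_shift) +
    rnorm3(nrow(true_lm), cfg$sigma_coreg_mm)
  coreg <- data.frame(
    case_id = case_id[lci], set = "coreg",
    label = paste0(SPINAL_LEVELS[lli], "_bb", rep(seq_len(8L), nv)),
    level = SPINAL_LEVELS[lli],
    src_x = coreg_src[, 1], src_y = coreg_src[, 2], src_z = coreg_src[, 3],
    dst_x = coreg_dst[, 1], dst_y = coreg_dst[, 2], dst_z = coreg_dst[, 3],
    stringsAsFactors = FALSE
  )

  # reference-screw fiducials for patient registration (2 per vertebra,
  # cranial-plating screws on the laminae); patient frame truth == navCT
  fci <- rep(vert_case, each = 2L)
  fli <- rep(vert_level, each = 2L)
  fsign <- rep(c(1, -1), nv)
  true_fid <- cbind(10 * fsign, 38, level_z(fli) + 5)
  fid_src <- true_fid + rnorm3(nrow(true_fid), cfg$sigma_fle_mm)
  fid_dst <- true_fid + rnorm3(nrow(true_fid), cfg$sigma_fle_mm)
  fid <- data.frame(
    case_id = case_id[fci], set = "patient_fiducial",
    label = paste0(SPINAL_LEVELS[fli], "_ref", ifelse(fsign > 0, "L", "R")),
    level = SPINAL_LEVELS[fli],
    src_x = fid_src[, 1], src_y = fid_src[, 2], src_z = fid_src[, 3],
    dst_x = fid_dst[, 1], dst_y = fid_dst[, 2], dst_z = fid_dst[, 3],
    stringsAsFactors = FALSE
  )

  # held-out targets for the navigation TRE: the true screw head points
  tgt <- data.frame(
    case_id = case_id[sci], set = "tre_target", label = screw_id, level = lev,
    src_x = head_p[, 1], src_y = head_p[, 2], src_z = head_p[, 3],
    dst_x = head_p[, 1], dst_y = head_p[, 2], dst_z = head_p[, 3],
    stringsAsFactors = FALSE
  )
  landmarks <- rbind(coreg, fid, tgt)
  rownames(landmarks) <- NULL

  # ---- covariates -----------------------------------------------------------
  age <- round(pmin(pmax(stats::rnorm(nc, cfg$age_mean, cfg$age_sd), 40), 90))
  weight <- pmin(pmax(stats::rnorm(nc, cfg$weight_mean, cfg$weight_sd), 50), 130)
  height <- pmin(pmax(stats::rnorm(nc, cfg$height_mean, cfg$height_sd), 145), 200)
  covariates <- data.frame(
    case_id = case_id, age = age,
    weight_kg = round(weight, 1), height_cm = round(height, 1),
    bmi = round(weight / (height / 100)^2, 1),
    diagnosis = sample(names(cfg$diagnosis_mix), nc, replace = TRUE,
                       prob = cfg$diagnosis_mix),
    stringsAsFactors = FALSE
  )

  # ---- ground truth ---------------------------------------------------------
  transforms <- lapply(seq_len(nc), function(i) {
    rigid_transform(matrix(R[i, ], 3, 3, byrow = TRUE), Tt[i, ],
                    source_frame = "navCT", target_frame = "controlCT")
  })
  names(transforms) <- case_id
  true_tre <- vapply(seq_len(nc), function(i) {
    f <- fid[fid$case_id == case_id[i], ]
    tg <- tgt[tgt$case_id == case_id[i], ]
    r <- fit_rigid_landmarks(landmark_set(
      source = as.matrix(f[, c("src_x", "src_y", "src_z")]),
      target = as.matrix(f[, c("dst_x", "dst_y", "dst_z")]),
      source_frame = "patient", target_frame = "navCT", labels = f$label
    ))
    target_registration_error(r,
                              as.matrix(tg[, c("src_x", "src_y", "src_z")]),
                              as.matrix(tg[, c("dst_x", "dst_y", "dst_z")]))
  }, numeric(1))
  gt_cases <- data.frame(
    case_id = case_id,
    n_segments = nseg,
    caudal_level = SPINAL_LEVELS[caudal],
    cranial_level = SPINAL_LEVELS[cranial_idx],
    shifted = shift_case,
    shift_level = ifelse(shift_case, SPINAL_LEVELS[cranial_idx], NA_character_),
    shift_mm = ifelse(shift_case, cfg$per_level_shift_mm, 0),
    true_tre_mm = true_tre,
    stringsAsFactors = FALSE
  )
  gt_screws <- data.frame(
    case_id = case_id[sci], screw_id = screw_id, level = lev, side = side,
    head_noise_x = dh[, 1], head_noise_y = dh[, 2], head_noise_z = dh[, 3],
    true_head_mad_mm = sqrt(rowSums(dh^2)),
    true_tip_mad_mm = sqrt(rowSums((dh + len * (dir_f - dir_p))^2)),
    true_tilt_deg = tilt * 180 / pi,
    stringsAsFactors = FALSE
  )

  structure(
    list(config = cfg, screws = screws, corridors = corridors,
         landmarks = landmarks, covariates = covariates,
         ground_truth = list(cases = gt_cases, transforms = transforms,
                             screws = gt_screws)),
    class = "synthetic_cohort"
  )
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort: %d cases, %d screws, seed %d>\n",
              x$config$n_cases, nrow(x$screws) / 2L, x$config$seed))
  print(table(level = x$screws$level[x$screws$role == "planned"]))
  invisible(x)
}

# ---- export / import --------------------------------------------------------

#' Write a synthetic cohort to a directory of plain-text files
#'
#' Emits `screws.csv`, `corridors.csv`, `landmarks.csv`, `covariates.csv`,
#' `ground_truth.json` (schema version 1) and `config.json`. The file set is
#' re-importable losslessly (coordinates to better than 1e-9 mm) via
#' [import_cohort()].
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
export_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(cohort$screws, file.path(dir, "screws.csv"), row.names = FALSE)
  utils::write.csv(cohort$corridors, file.path(dir, "corridors.csv"), row.names = FALSE)
  utils::write.csv(cohort$landmarks, file.path(dir, "landmarks.csv"), row.names = FALSE)
  utils::write.csv(cohort$covariates, file.path(dir, "covariates.csv"), row.names = FALSE)
  gt <- cohort$ground_truth
  jsonlite::write_json(
    list(
      schema_version = 1L,
      cases = gt$cases,
      transforms = lapply(gt$transforms, function(t) {
        list(matrix = as.vector(t(rbind(cbind(t$rotation, t$translation),
                                        c(0, 0, 0, 1)))),
             source_frame = t$source_frame, target_frame = t$target_frame)
      }),
      screws = gt$screws
    ),
    file.path(dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA
  )
  # named vectors must go out as JSON objects (write_json drops vector names)
  cfg_ser <- lapply(unclass(cohort$config), function(v) {
    if (!is.null(names(v))) as.list(v) else v
  })
  jsonlite::write_json(cfg_ser, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname export_cohort
#' @export
import_cohort <- function(dir) {
  cfg_raw <- jsonlite::read_json(file.path(dir, "config.json"), simplifyVector = TRUE)
  cfg <- do.call(simulation_config, lapply(cfg_raw, function(v) {
    if (is.list(v)) unlist(v) else v
  }))
  gt_raw <- jsonlite::read_json(file.path(dir, "ground_truth.json"),
                                simplifyVector = TRUE)
  transforms <- lapply(gt_raw$transforms, function(o) {
    m <- matrix(as.numeric(o$matrix), 4, 4, byrow = TRUE)
    rigid_transform(m[1:3, 1:3], m[1:3, 4], o$source_frame, o$target_frame)
  })
  structure(
    list(config = cfg,
         screws = screw_table(utils::read.csv(file.path(dir, "screws.csv"),
                                              stringsAsFactors = FALSE)),
         corridors = utils::read.csv(file.path(dir, "corridors.csv"),
                                     stringsAsFactors = FALSE),
         landmarks = utils::read.csv(file.path(dir, "landmarks.csv"),
                                     stringsAsFactors = FALSE),
         covariates = utils::read.csv(file.path(dir, "covariates.csv"),
                                      stringsAsFactors = FALSE),
         ground_truth = list(cases = gt_raw$cases, transforms = transforms,
                             screws = gt_raw$screws)),
    class = "synthetic_cohort"
  )
}
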