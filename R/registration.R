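# Landmark-based rigid registration. Stands in for both the intraoperative
# point-to-point patient registration (reference screws on the laminae) and
# the planning-to-control CT co-registration: the downstream mathematics only
# needs the rigid transform, so paired landmarks replace intensity-based
# image registration here.

#' Paired landmark set for rigid registration
#'
#' @param source,target `n x 3` coordinate matrices or `pt3` objects; pairing
#'   is positional. At least 3 non-collinear pairs are required for fitting.
#' @param source_frame,target_frame Frame tags (taken from the `pt3` inputs
#'   when omitted).
#' @param labels Optional character labels, one per landmark.
#' @param level Optional spinal-level tag per landmark (used for per-level
#'   co-registration verification).
#' @return A `landmark_set` object.
#' @export
landmark_set <- function(source, target, source_frame = NULL,
                         target_frame = NULL, labels = NULL, level = NULL) {
  if (inherits(source, "pt3")) {
    source_frame <- source_frame %||% pt_frame(source)
    source <- coords(source)
  }
  if (inherits(target, "pt3")) {
    target_frame <- target_frame %||% pt_frame(target)
    target <- coords(target)
  }
  source <- as.matrix(source)
  target <- as.matrix(target)
  if (nrow(source) != nrow(target)) {
    stop("source and target must contain the same number of landmarks")
  }
  n <- nrow(source)
  if (is.null(labels)) labels <- sprintf("lm%02d", seq_len(n))
  if (!is.null(level) && length(level) != n) {
    stop("`level` must have one entry per landmark")
  }
  structure(
    list(labels = as.character(labels), level = level,
         source = source, target = target,
         source_frame = source_frame %||% "source",
         target_frame = target_frame %||% "target"),
    class = "landmark_set"
  )
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.landmark_set <- function(x, ...) {
  cat(sprintf("<landmark_set: %d pairs, '%s' -> '%s'>\n",
              nrow(x$source), x$source_frame, x$target_frame))
  invisible(x)
}

#' Least-squares rigid registration of paired landmarks
#'
#' Fits the proper rigid transform (rotation + translation, no scaling or
#' reflection) minimizing the sum of squared distances between transformed
#' source landmarks and their targets: centroid alignment followed by SVD of
#' the cross-covariance with determinant sign correction, so the solution is
#' always a proper rotation even when noise would make the naive SVD solution
#' a reflection. The fiducial registration error (FRE) is the RMS of the
#' post-fit residuals.
#'
#' @param lm A `landmark_set` with at least 3 non-collinear pairs.
#' @return A `registration_result`: list with `transform`
#'   (`rigid_transform`), `fre_mm`, `per_landmark_residuals_mm`, `tre_mm`
#'   (`NA` until evaluated via [target_registration_error()]).
#' @export
fit_rigid_landmarks <- function(lm) {
  stopifnot(inherits(lm, "landmark_set"))
  X <- lm$source
  Y <- lm$target
  if (nrow(X) < 3L) {
    stop_navscrew("rigid registration needs at least 3 landmark pairs",
                  "navscrew_underdetermined_error")
  }
  cx <- colMeans(X)
  cy <- colMeans(Y)
  Xc <- sweep(X, 2L, cx)
  Yc <- sweep(Y, 2L, cy)
  sv_x <- svd(Xc)$d
  if (sv_x[2] < 1e-8 * max(sv_x[1], 1)) {
    stop_navscrew("landmarks are collinear: rotation is underdetermined",
                  "navscrew_underdetermined_error")
  }
  H <- crossprod(Xc, Yc)  # 3x3 cross-covariance
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  tr <- cy - as.numeric(R %*% cx)
  transform <- rigid_transform(R, tr, lm$source_frame, lm$target_frame)
  mapped <- X %*% t(R)
  mapped <- sweep(mapped, 2L, tr, "+")
  res <- sqrt(rowSums((mapped - Y)^2))
  structure(
    list(transform = transform,
         fre_mm = sqrt(mean(res^2)),
         per_landmark_residuals_mm = stats::setNames(res, lm$labels),
         landmark_level = lm$level,
         tre_mm = NA_real_),
    class = "registration_result"
  )
}

#' @export
print.registration_result <- function(x, ...) {
  cat(sprintf("<registration_result: '%s' -> '%s', FRE %.4f mm, %d landmarks>\n",
              x$transform$source_frame, x$transform$target_frame,
              x$fre_mm, length(x$per_landmark_residuals_mm)))
  if (!is.na(x$tre_mm)) cat(sprintf("  TRE %.4f mm\n", x$tre_mm))
  invisible(x)
}

#' Target registration error at held-out targets
#'
#' Mean (not RMS) Euclidean distance between transformed source targets and
#' their true target-frame positions, matching how navigation systems report
#' a mean registration error at points of interest. Targets must be disjoint
#' from the landmarks used for fitting for the value to estimate TRE.
#'
#' @param r A `registration_result`.
#' @param targets_source `pt3` (or matrix) of target points in the source frame.
#' @param targets_truth `pt3` (or matrix) of their true positions in the
#'   target frame.
#' @return Mean distance in mm; also stored in the returned result when
#'   assigned.
#' @export
target_registration_error <- function(r, targets_source, targets_truth) {
  stopifnot(inherits(r, "registration_result"))
  if (inherits(targets_source, "pt3")) {
    if (!identical(pt_frame(targets_source), r$transform$source_frame)) {
      stop_frame_error("targets_source is not in the registration source frame")
    }
    targets_source <- coords(targets_source)
  }
  if (inherits(targets_truth, "pt3")) {
    if (!identical(pt_frame(targets_truth), r$transform$target_frame)) {
      stop_frame_error("targets_truth is not in the registration target frame")
    }
    targets_truth <- coords(targets_truth)
  }
  targets_source <- as.matrix(targets_source)
  targets_truth <- as.matrix(targets_truth)
  if (nrow(targets_source) == 0L) {
    stop_navscrew("empty target list", "navscrew_empty_input_error")
  }
  if (nrow(targets_source) != nrow(targets_truth)) {
    stop("target lists must be paired")
  }
  mapped <- targets_source %*% t(r$transform$rotation)
  mapped <- sweep(mapped, 2L, r$transform$translation, "+")
  mean(sqrt(rowSums((mapped - targets_truth)^2)))
}

#' Per-level RMS residuals of a fitted co-registration
#'
#' @param r A `registration_result` fitted on a landmark set that carried
#'   `level` tags.
#' @return Named numeric vector: RMS residual (mm) per spinal level.
#' @export
per_level_residuals <- function(r) {
  stopifnot(inherits(r, "registration_result"))
  if (is.null(r$landmark_level)) {
    stop("registration was fitted on landmarks without level tags")
  }
  res2 <- r$per_landmark_residuals_mm^2
  out <- tapply(res2, r$landmark_level, function(v) sqrt(mean(v)))
  out[order(match(names(out), SPINAL_LEVELS))]
}

#' Verify a co-registration level by level
#'
#' A spinal level is flagged when its residual strictly exceeds `tau_mm`
#' (equality passes); under the default policy a case is excluded when any
#' instrumented level is flagged. This emulates the visual verification of
#' co-registration quality at the vertebral-body boundaries, with a numeric
#' surrogate threshold.
#'
#' @param per_level_residual_mm Named non-negative numeric vector, mm per level.
#' @param tau_mm Positive threshold (default 2 mm).
#' @return A `coreg_verdict`: list with `per_level_residual_mm`,
#'   `flagged_levels`, `case_excluded`.
#' @export
verify_coregistration <- function(per_level_residual_mm, tau_mm = 2) {
  if (any(per_level_residual_mm < 0) || any(!is.finite(per_level_residual_mm))) {
    stop_navscrew("residuals must be finite and non-negative",
                  "navscrew_validation_error")
  }
  if (!is.numeric(tau_mm) || length(tau_mm) != 1L || tau_mm <= 0) {
    stop_navscrew("`tau_mm` must be a positive scalar", "navscrew_validation_error")
  }
  flagged <- names(per_level_residual_mm)[per_level_residual_mm > tau_mm]
  structure(
    list(per_level_residual_mm = per_level_residual_mm,
         flagged_levels = flagged,
         case_excluded = length(flagged) > 0L),
    class = "coreg_verdict"
  )
}

#' @export
print.coreg_verdict <- function(x, ...) {
  cat("<coreg_verdict>\n")
  print(round(x$per_level_residual_mm, 3))
  if (x$case_excluded) {
    cat("EXCLUDED; flagged level(s):", paste(x$flagged_levels, collapse = ", "), "\n")
  } else {
    cat("co-registration accepted\n")
  }
  invisible(x)
}

# ---- file formats -----------------------------------------------------------

#' Read / write landmark CSV files
#'
#' Schema: columns `label`, `level` (optional, may be empty), `src_x`,
#' `src_y`, `src_z`, `dst_x`, `dst_y`, `dst_z` (mm), plus optional `case_id`
#' and `set` columns when several landmark sets share one file. Header
#' required; comma separator; decimal point.
#'
#' @param path File path.
#' @param source_frame,target_frame Frame tags to attach on read.
#' @return `read_landmarks()` returns a data.frame;
#'   [as_landmark_set()] converts (a subset of) it to a `landmark_set`.
#' @export
read_landmarks <- function(path, source_frame = "navCT", target_frame = "controlCT") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("label", "src_x", "src_y", "src_z", "dst_x", "dst_y", "dst_z")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop_navscrew(sprintf("landmark file is missing column(s): %s",
                          paste(missing_cols, collapse = ", ")),
                  "navscrew_validation_error")
  }
  attr(df, "source_frame") <- source_frame
  attr(df, "target_frame") <- target_frame
  df
}

#' @rdname read_landmarks
#' @param df Landmark data.frame as returned by `read_landmarks()`.
#' @export
as_landmark_set <- function(df, source_frame = NULL, target_frame = NULL) {
  landmark_set(
    source = as.matrix(df[, c("src_x", "src_y", "src_z")]),
    target = as.matrix(df[, c("dst_x", "dst_y", "dst_z")]),
    source_frame = source_frame %||% attr(df, "source_frame") %||% "navCT",
    target_frame = target_frame %||% attr(df, "target_frame") %||% "controlCT",
    labels = df$label,
    level = if ("level" %in% names(df) && !all(is.na(df$level))) df$level else NULL
  )
}

#' Read / write a rigid transform as JSON
#'
#' The on-disk format is a 4x4 homogeneous row-major matrix (mm) plus
#' explicit `source_frame` / `target_frame` tags, avoiding axis-order
#' ambiguity.
#'
#' @param t A `rigid_transform` (for writing).
#' @param path File path.
#' @return `read_transform_json()` returns a `rigid_transform`.
#' @export
write_transform_json <- function(t, path) {
  stopifnot(inherits(t, "rigid_transform"))
  m <- rbind(cbind(t$rotation, t$translation), c(0, 0, 0, 1))
  jsonlite::write_json(
    list(matrix = as.vector(t(m)), source_frame = t$source_frame,
         target_frame = t$target_frame),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_transform_json
#' @export
read_transform_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  m <- matrix(as.numeric(obj$matrix), nrow = 4, byrow = TRUE)
  rigid_transform(m[1:3, 1:3], m[1:3, 4], obj$source_frame, obj$target_frame)
}
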