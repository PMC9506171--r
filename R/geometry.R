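# Frame-tagged 3D primitives. All coordinates are millimetres in a
# right-handed LPS-style patient frame; frames are opaque string tags
# ("navCT", "controlCT") and every cross-frame operation is gated on tag
# equality so that silently mixing un-coregistered frames is impossible.

#' Signal a coordinate-frame mismatch
#' @noRd
stop_frame_error <- function(msg) {
  stop(errorCondition(msg, class = c("navscrew_frame_error", "navscrew_error")))
}

#' @noRd
stop_navscrew <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "navscrew_error")))
}

#' Frame-tagged 3D point set
#'
#' Constructs one or more 3D points (millimetres) tagged with the coordinate
#' frame they live in. Points are stored as an `n x 3` matrix with a `frame`
#' attribute; all geometric operations refuse to combine points from
#' different frames.
#'
#' @param x Numeric vector of x coordinates, or an `n x 3` matrix (or length-3
#'   vector) of coordinates when `y` and `z` are missing.
#' @param y,z Numeric vectors of y and z coordinates (mm).
#' @param frame Non-empty string naming the coordinate frame.
#' @return A `pt3` object: `n x 3` numeric matrix with a `frame` attribute.
#' @examples
#' p <- pt3(0, 0, 0, frame = "navCT")
#' q <- pt3(1, 2, 2, frame = "navCT")
#' euclidean_mad(p, q)  # 3 mm
#' @export
pt3 <- function(x, y = NULL, z = NULL, frame) {
  if (is.null(y)) {
    m <- if (is.matrix(x)) x else matrix(as.numeric(x), ncol = 3, byrow = TRUE)
  } else {
    m <- cbind(as.numeric(x), as.numeric(y), as.numeric(z))
  }
  if (ncol(m) != 3L) stop("points must have three coordinates")
  if (!all(is.finite(m))) stop("point coordinates must be finite")
  if (!is.character(frame) || length(frame) != 1L || !nzchar(frame)) {
    stop("`frame` must be a single non-empty string")
  }
  colnames(m) <- c("x", "y", "z")
  structure(m, frame = frame, class = "pt3")
}

#' @export
print.pt3 <- function(x, ...) {
  cat(sprintf("<pt3: %d point(s) in frame '%s'>\n", nrow(x), pt_frame(x)))
  print(coords(x))
  invisible(x)
}

#' Frame tag of a point set or unit vector
#' @param p A `pt3` or `unit3` object.
#' @return The frame tag (string).
#' @export
pt_frame <- function(p) attr(p, "frame")

#' Raw coordinate matrix of a `pt3`/`unit3`
#' @param p A `pt3` or `unit3` object.
#' @return An `n x 3` numeric matrix.
#' @export
coords <- function(p) {
  m <- unclass(p)
  attr(m, "frame") <- NULL
  m
}

#' Frame-tagged unit direction vector(s)
#'
#' @param x,y,z Components, or `x` an `n x 3` matrix when `y`, `z` missing.
#' @param frame Frame tag.
#' @param normalize If `TRUE`, rescale rows to unit norm; otherwise rows must
#'   already have Euclidean norm 1 within `1e-9`.
#' @return A `unit3` object (`n x 3` matrix, `frame` attribute).
#' @export
unit3 <- function(x, y = NULL, z = NULL, frame, normalize = FALSE) {
  p <- pt3(x, y, z, frame = frame)
  m <- coords(p)
  nrm <- sqrt(rowSums(m^2))
  if (normalize) {
    if (any(nrm < 1e-12)) {
      stop_navscrew("cannot normalize a zero vector", "navscrew_degenerate_error")
    }
    m <- m / nrm
  } else if (any(abs(nrm - 1) > 1e-9)) {
    stop("unit3 components must have unit Euclidean norm (within 1e-9)")
  }
  structure(m, frame = frame, class = "unit3")
}

#' @export
print.unit3 <- function(x, ...) {
  cat(sprintf("<unit3: %d direction(s) in frame '%s'>\n", nrow(x), pt_frame(x)))
  print(coords(x))
  invisible(x)
}

#' @noRd
check_same_frame <- function(a, b, what) {
  fa <- pt_frame(a)
  fb <- pt_frame(b)
  if (!identical(fa, fb)) {
    stop_frame_error(sprintf(
      "%s requires both operands in one frame (got '%s' vs '%s'); apply a rigid_transform first",
      what, fa, fb
    ))
  }
}

#' Euclidean distance between corresponding 3D points
#'
#' The minimal absolute distance (MAD) between paired points:
#' `sqrt(d(x)^2 + d(y)^2 + d(z)^2)`. This is the per-point deviation metric
#' used for planned-versus-final screw head and tip comparisons.
#'
#' @param a,b `pt3` objects in the same frame, with matching row counts (or
#'   either of length one, which is recycled).
#' @return Numeric vector of distances (mm), non-negative.
#' @export
euclidean_mad <- function(a, b) {
  stopifnot(inherits(a, "pt3"), inherits(b, "pt3"))
  check_same_frame(a, b, "euclidean_mad")
  ma <- coords(a)
  mb <- coords(b)
  if (nrow(ma) != nrow(mb)) {
    if (nrow(ma) == 1L) ma <- ma[rep(1L, nrow(mb)), , drop = FALSE]
    else if (nrow(mb) == 1L) mb <- mb[rep(1L, nrow(ma)), , drop = FALSE]
    else stop("point sets must have matching lengths")
  }
  sqrt(rowSums((ma - mb)^2))
}

#' Angle between unit direction vectors, in degrees
#'
#' Computed as the arccosine of the dot product, clamped to `[-1, 1]`;
#' results lie in `[0, 180]` degrees and are not folded at 90 degrees.
#'
#' @param u,v `unit3` objects in the same frame (row counts matching, or
#'   either of length one).
#' @return Numeric vector of angles in degrees.
#' @export
angle_between_deg <- function(u, v) {
  stopifnot(inherits(u, "unit3"), inherits(v, "unit3"))
  check_same_frame(u, v, "angle_between_deg")
  mu <- coords(u)
  mv <- coords(v)
  if (nrow(mu) != nrow(mv)) {
    if (nrow(mu) == 1L) mu <- mu[rep(1L, nrow(mv)), , drop = FALSE]
    else if (nrow(mv) == 1L) mv <- mv[rep(1L, nrow(mu)), , drop = FALSE]
    else stop("direction sets must have matching lengths")
  }
  d <- pmin(1, pmax(-1, rowSums(mu * mv)))
  acos(d) * 180 / pi
}

#' Proper rigid transform between two tagged frames
#'
#' @param rotation 3x3 rotation matrix; must be orthonormal with determinant
#'   +1 within `1e-9` (reflections are rejected).
#' @param translation Length-3 numeric translation (mm).
#' @param source_frame,target_frame Frame tags; the transform maps
#'   source-frame coordinates onto the target frame.
#' @return A `rigid_transform` object.
#' @export
rigid_transform <- function(rotation, translation, source_frame, target_frame) {
  rotation <- as.matrix(rotation)
  translation <- as.numeric(translation)
  stopifnot(all(dim(rotation) == c(3L, 3L)), length(translation) == 3L,
            all(is.finite(rotation)), all(is.finite(translation)))
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-9) {
    stop("`rotation` must be orthonormal within 1e-9")
  }
  if (abs(det(rotation) - 1) > 1e-9) {
    stop("`rotation` must be a proper rotation (det +1); reflections are not allowed")
  }
  for (f in list(source_frame, target_frame)) {
    if (!is.character(f) || length(f) != 1L || !nzchar(f)) {
      stop("frame tags must be single non-empty strings")
    }
  }
  structure(
    list(rotation = rotation, translation = translation,
         source_frame = source_frame, target_frame = target_frame),
    class = "rigid_transform"
  )
}

#' Identity transform between two frames (or within one)
#' @param source_frame,target_frame Frame tags.
#' @return A `rigid_transform`.
#' @export
identity_transform <- function(source_frame, target_frame = source_frame) {
  rigid_transform(diag(3), c(0, 0, 0), source_frame, target_frame)
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("<rigid_transform: '%s' -> '%s'>\n", x$source_frame, x$target_frame))
  cat("rotation:\n")
  print(round(x$rotation, 6))
  cat("translation (mm):", paste(round(x$translation, 4), collapse = ", "), "\n")
  invisible(x)
}

#' Apply a rigid transform to points
#'
#' @param t A `rigid_transform`.
#' @param p A `pt3` in `t$source_frame`.
#' @return A `pt3` in `t$target_frame`.
#' @export
apply_transform <- function(t, p) {
  stopifnot(inherits(t, "rigid_transform"), inherits(p, "pt3"))
  if (!identical(pt_frame(p), t$source_frame)) {
    stop_frame_error(sprintf(
      "transform expects points in frame '%s' but got '%s'",
      t$source_frame, pt_frame(p)
    ))
  }
  m <- coords(p) %*% t(t$rotation)
  m <- sweep(m, 2L, t$translation, "+")
  pt3(m, frame = t$target_frame)
}

#' Rotate unit direction vectors into a transform's target frame
#'
#' Directions are free vectors: only the rotation part applies.
#'
#' @param t A `rigid_transform`.
#' @param u A `unit3` in `t$source_frame`.
#' @return A `unit3` in `t$target_frame`.
#' @export
apply_transform_dir <- function(t, u) {
  stopifnot(inherits(t, "rigid_transform"), inherits(u, "unit3"))
  if (!identical(pt_frame(u), t$source_frame)) {
    stop_frame_error(sprintf(
      "transform expects directions in frame '%s' but got '%s'",
      t$source_frame, pt_frame(u)
    ))
  }
  unit3(coords(u) %*% t(t$rotation), frame = t$target_frame, normalize = TRUE)
}

#' Invert a rigid transform
#' @param t A `rigid_transform`.
#' @return The inverse `rigid_transform` (frames swapped).
#' @export
invert_transform <- function(t) {
  stopifnot(inherits(t, "rigid_transform"))
  rt <- t(t$rotation)
  rigid_transform(rt, -as.numeric(rt %*% t$translation),
                  source_frame = t$target_frame, target_frame = t$source_frame)
}

#' Compose two rigid transforms
#'
#' `compose_transform(b, a)` applies `a` first, then `b`; `a`'s target frame
#' must equal `b`'s source frame.
#'
#' @param b,a `rigid_transform` objects.
#' @return The composed `rigid_transform` mapping `a$source_frame` to
#'   `b$target_frame`.
#' @export
compose_transform <- function(b, a) {
  stopifnot(inherits(a, "rigid_transform"), inherits(b, "rigid_transform"))
  if (!identical(a$target_frame, b$source_frame)) {
    stop_frame_error(sprintf(
      "cannot compose: first transform targets '%s' but second expects '%s'",
      a$target_frame, b$source_frame
    ))
  }
  rigid_transform(b$rotation %*% a$rotation,
                  as.numeric(b$rotation %*% a$translation) + b$translation,
                  source_frame = a$source_frame, target_frame = b$target_frame)
}

#' Rotation matrix about an arbitrary axis
#'
#' Rodrigues' formula; used to build tilts and random proper rotations.
#'
#' @param axis Length-3 numeric axis (need not be unit).
#' @param angle_deg Rotation angle in degrees (right-handed).
#' @return A 3x3 rotation matrix.
#' @export
rotation_about_axis <- function(axis, angle_deg) {
  axis <- as.numeric(axis)
  n <- sqrt(sum(axis^2))
  if (n < 1e-12) stop("rotation axis must be non-zero")
  k <- axis / n
  th <- angle_deg * pi / 180
  K <- matrix(c(0, k[3], -k[2], -k[3], 0, k[1], k[2], -k[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# ---- screws -----------------------------------------------------------------

SPINAL_LEVELS <- c("L1", "L2", "L3", "L4", "L5", "S1")

#' Build a screw table
#'
#' A screw table is a data.frame with one row per screw (planned or final)
#' and the columns `case_id`, `screw_id`, `level` (L1-S1), `side`
#' (left/right), `role` (planned/final), `head_x/y/z`, `tip_x/y/z`,
#' `diameter_mm`, `length_mm`, `frame`. `screw()` builds a one-row table;
#' `screw_table()` validates any data.frame in this schema. The recorded
#' `length_mm` must agree with the head-tip distance within 1 mm (a warning
#' is raised above that, an error above 5 mm).
#'
#' @param case_id,screw_id Identifiers.
#' @param level Spinal level, one of L1-S1.
#' @param side `"left"` or `"right"`.
#' @param role `"planned"` or `"final"`.
#' @param head,tip Length-3 numeric coordinates (mm) or `pt3` of length 1.
#' @param diameter_mm,length_mm Screw dimensions (mm), positive.
#' @param frame Frame tag; head and tip share it.
#' @return A validated screw table (data.frame).
#' @export
screw <- function(case_id, screw_id, level, side, role, head, tip,
                  diameter_mm, length_mm, frame) {
  if (inherits(head, "pt3")) {
    if (!identical(pt_frame(head), frame)) {
      stop_frame_error("`head` frame does not match `frame`")
    }
    head <- as.numeric(coords(head))
  }
  if (inherits(tip, "pt3")) {
    if (!identical(pt_frame(tip), frame)) {
      stop_frame_error("`tip` frame does not match `frame`")
    }
    tip <- as.numeric(coords(tip))
  }
  screw_table(data.frame(
    case_id = case_id, screw_id = screw_id, level = level, side = side,
    role = role, head_x = head[1], head_y = head[2], head_z = head[3],
    tip_x = tip[1], tip_y = tip[2], tip_z = tip[3],
    diameter_mm = diameter_mm, length_mm = length_mm, frame = frame,
    stringsAsFactors = FALSE
  ))
}

SCREW_COLUMNS <- c("case_id", "screw_id", "level", "side", "role",
                   "head_x", "head_y", "head_z", "tip_x", "tip_y", "tip_z",
                   "diameter_mm", "length_mm", "frame")

#' @rdname screw
#' @param x A data.frame in the screw-table schema.
#' @export
screw_table <- function(x) {
  stopifnot(is.data.frame(x))
  missing_cols <- setdiff(SCREW_COLUMNS, names(x))
  if (length(missing_cols)) {
    stop_navscrew(
      sprintf("screw table is missing column(s): %s",
              paste(missing_cols, collapse = ", ")),
      "navscrew_validation_error"
    )
  }
  if (nrow(x) == 0L) return(x)
  num_cols <- c("head_x", "head_y", "head_z", "tip_x", "tip_y", "tip_z",
                "diameter_mm", "length_mm")
  for (cl in num_cols) {
    v <- x[[cl]]
    if (!is.numeric(v) || !all(is.finite(v))) {
      bad <- if (is.numeric(v)) which(!is.finite(v))[1] else 1L
      stop_navscrew(
        sprintf("screw table row %d: column '%s' is not finite numeric", bad, cl),
        "navscrew_validation_error"
      )
    }
  }
  bad_level <- which(!x$level %in% SPINAL_LEVELS)
  if (length(bad_level)) {
    stop_navscrew(
      sprintf("screw table row %d: unknown level '%s' (expected %s)",
              bad_level[1], x$level[bad_level[1]],
              paste(SPINAL_LEVELS, collapse = "/")),
      "navscrew_validation_error"
    )
  }
  bad_side <- which(!x$side %in% c("left", "right"))
  if (length(bad_side)) {
    stop_navscrew(sprintf("screw table row %d: side must be left/right", bad_side[1]),
                  "navscrew_validation_error")
  }
  bad_role <- which(!x$role %in% c("planned", "final"))
  if (length(bad_role)) {
    stop_navscrew(sprintf("screw table row %d: role must be planned/final", bad_role[1]),
                  "navscrew_validation_error")
  }
  if (any(x$diameter_mm <= 0) || any(x$length_mm <= 0)) {
    stop_navscrew("screw dimensions must be positive", "navscrew_validation_error")
  }
  d <- sqrt((x$head_x - x$tip_x)^2 + (x$head_y - x$tip_y)^2 +
              (x$head_z - x$tip_z)^2)
  if (any(d < 1e-9)) {
    stop_navscrew(
      sprintf("screw table row %d: head and tip coincide (degenerate screw)",
              which(d < 1e-9)[1]),
      "navscrew_degenerate_error"
    )
  }
  mismatch <- abs(d - x$length_mm)
  if (any(mismatch > 5)) {
    i <- which(mismatch > 5)[1]
    stop_navscrew(
      sprintf("screw table row %d (%s/%s): head-tip distance %.2f mm differs from length_mm %.2f by > 5 mm",
              i, x$case_id[i], x$screw_id[i], d[i], x$length_mm[i]),
      "navscrew_validation_error"
    )
  }
  if (any(mismatch > 1)) {
    i <- which(mismatch > 1)
    warning(sprintf(
      "%d screw(s) have head-tip distance differing from length_mm by > 1 mm (first: %s/%s)",
      length(i), x$case_id[i[1]], x$screw_id[i[1]]
    ))
  }
  x
}

#' Head / tip points and axis of screws
#'
#' `screw_heads()` and `screw_tips()` extract frame-tagged point sets from a
#' screw table; `axis_of()` returns the head-to-tip unit direction (the drill
#' path direction) for each screw.
#'
#' @param s A screw table (all rows must share one frame).
#' @return `pt3` / `unit3` objects with one row per screw.
#' @export
screw_heads <- function(s) {
  f <- unique(s$frame)
  if (length(f) != 1L) stop_frame_error("screw table mixes frames")
  pt3(cbind(s$head_x, s$head_y, s$head_z), frame = f)
}

#' @rdname screw_heads
#' @export
screw_tips <- function(s) {
  f <- unique(s$frame)
  if (length(f) != 1L) stop_frame_error("screw table mixes frames")
  pt3(cbind(s$tip_x, s$tip_y, s$tip_z), frame = f)
}

#' @rdname screw_heads
#' @export
axis_of <- function(s) {
  h <- coords(screw_heads(s))
  t_ <- coords(screw_tips(s))
  d <- t_ - h
  n <- sqrt(rowSums(d^2))
  if (any(n < 1e-9)) {
    stop_navscrew("degenerate screw: head and tip coincide", "navscrew_degenerate_error")
  }
  unit3(d / n, frame = unique(s$frame))
}

#' Map a screw table into another frame
#'
#' Applies a rigid transform to head and tip points and retags the frame.
#'
#' @param t A `rigid_transform` whose source frame matches the table's frame.
#' @param s A screw table.
#' @return The transformed screw table (frame = `t$target_frame`).
#' @export
transform_screws <- function(t, s) {
  h <- apply_transform(t, screw_heads(s))
  tp <- apply_transform(t, screw_tips(s))
  s[, c("head_x", "head_y", "head_z")] <- coords(h)
  s[, c("tip_x", "tip_y", "tip_z")] <- coords(tp)
  s$frame <- t$target_frame
  s
}
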