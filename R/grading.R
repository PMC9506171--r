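# Geometric Gertzbein-Robbins surrogate. The published grading is a visual
# consensus read of "mm of cortical breach"; here the pedicle is modeled as
# an elliptical cylinder (the safe corridor) and the screw as a finite
# cylinder, and the breach is the maximum penetration of the screw surface
# outside the corridor boundary within the corridor's axial extent. Grades:
# A (no breach), B (<2 mm), C (2-<4), D (4-<6), E (>=6); A and B are
# clinically acceptable.

#' Pedicle corridor (elliptical safe-corridor model)
#'
#' The corridor is an elliptical cylinder: `axis_point` + `axis_dir` define
#' the axis, `semi_axis_transverse_mm` / `semi_axis_sagittal_mm` the
#' cross-section semi-axes, and `axial_extent_mm` the pedicle segment along
#' the axis within which breach is evaluated. `ref_dir` is a reference
#' direction (default cranio-caudal, `(0,0,1)`) fixing the orientation of
#' the elliptical cross-section: the sagittal semi-axis lies along the
#' projection of `ref_dir` perpendicular to the axis. It transforms with the
#' corridor, so breach depths are invariant under common rigid transforms.
#'
#' @param level Spinal level (L1-S1).
#' @param axis_point `pt3` (one point) or length-3 numeric: a point on the
#'   corridor axis.
#' @param axis_dir `unit3` or length-3 numeric: axis direction.
#' @param semi_axis_transverse_mm,semi_axis_sagittal_mm Positive semi-axes (mm).
#' @param axial_extent_mm Length-2 numeric `(start, end)` along the axis from
#'   `axis_point`, start < end.
#' @param frame Frame tag (taken from `axis_point` when it is a `pt3`).
#' @param ref_dir Length-3 numeric reference direction (need not be unit);
#'   must not be parallel to `axis_dir`.
#' @param case_id,side Optional identifiers used when corridors are matched
#'   to screws in a cohort.
#' @return A `pedicle_corridor` object.
#' @export
pedicle_corridor <- function(level, axis_point, axis_dir,
                             semi_axis_transverse_mm, semi_axis_sagittal_mm,
                             axial_extent_mm, frame = NULL,
                             ref_dir = c(0, 0, 1),
                             case_id = NA_character_, side = NA_character_) {
  if (inherits(axis_point, "pt3")) {
    frame <- frame %||% pt_frame(axis_point)
    axis_point <- as.numeric(coords(axis_point))
  }
  if (inherits(axis_dir, "unit3")) {
    if (!is.null(frame) && !identical(pt_frame(axis_dir), frame)) {
      stop_frame_error("axis_dir frame does not match axis_point frame")
    }
    axis_dir <- as.numeric(coords(axis_dir))
  }
  axis_dir <- axis_dir / sqrt(sum(axis_dir^2))
  stopifnot(level %in% SPINAL_LEVELS,
            semi_axis_transverse_mm > 0, semi_axis_sagittal_mm > 0,
            length(axial_extent_mm) == 2L,
            axial_extent_mm[1] < axial_extent_mm[2])
  ref_dir <- as.numeric(ref_dir)
  if (sqrt(sum(ref_dir^2)) < 1e-9) {
    stop("`ref_dir` must be non-zero")
  }
  if (abs(sum(ref_dir * axis_dir)) / sqrt(sum(ref_dir^2)) > 1 - 1e-9) {
    # reference parallel to the axis leaves the cross-section orientation
    # undefined; fall back to whichever coordinate axis is least aligned
    ref_dir <- diag(3)[, which.min(abs(axis_dir))]
  }
  structure(
    list(level = level, case_id = case_id, side = side,
         axis_point = as.numeric(axis_point), axis_dir = axis_dir,
         ref_dir = ref_dir,
         semi_axis_transverse_mm = semi_axis_transverse_mm,
         semi_axis_sagittal_mm = semi_axis_sagittal_mm,
         axial_extent_mm = as.numeric(axial_extent_mm),
         frame = frame %||% "navCT"),
    class = "pedicle_corridor"
  )
}

#' @export
print.pedicle_corridor <- function(x, ...) {
  cat(sprintf("<pedicle_corridor %s %s: semi-axes %.1f x %.1f mm, extent [%.0f, %.0f] mm, frame '%s'>\n",
              x$level, ifelse(is.na(x$side), "", x$side),
              x$semi_axis_transverse_mm, x$semi_axis_sagittal_mm,
              x$axial_extent_mm[1], x$axial_extent_mm[2], x$frame))
  invisible(x)
}

#' Map a corridor into another frame
#' @param t A `rigid_transform` (source frame = corridor frame).
#' @param corridor A `pedicle_corridor`.
#' @return The transformed corridor.
#' @export
transform_corridor <- function(t, corridor) {
  stopifnot(inherits(t, "rigid_transform"), inherits(corridor, "pedicle_corridor"))
  if (!identical(corridor$frame, t$source_frame)) {
    stop_frame_error(sprintf("corridor is in frame '%s', transform expects '%s'",
                             corridor$frame, t$source_frame))
  }
  corridor$axis_point <- as.numeric(t$rotation %*% corridor$axis_point) + t$translation
  corridor$axis_dir <- as.numeric(t$rotation %*% corridor$axis_dir)
  corridor$ref_dir <- as.numeric(t$rotation %*% corridor$ref_dir)
  corridor$frame <- t$target_frame
  corridor
}

#' Signed distance from 2D points to an axis-aligned ellipse
#'
#' Euclidean distance to the ellipse boundary with semi-axes `a` (u) and `b`
#' (v); positive outside, negative inside. Solved by vectorized bisection on
#' the standard auxiliary equation for the closest boundary point.
#'
#' @param u,v Point coordinates (vectors).
#' @param a,b Semi-axes, positive scalars.
#' @return Numeric vector of signed distances.
#' @export
ellipse_signed_distance <- function(u, v, a, b) {
  stopifnot(a > 0, b > 0)
  if (abs(a - b) < 1e-12) {           # circular fast path: exact
    return(sqrt(u^2 + v^2) - a)
  }
  su <- sign(u); sv <- sign(v)
  # work in the first quadrant; nudge exact zeros so the auxiliary equation
  # keeps a root even for points on a principal axis inside the evolute
  au <- pmax(abs(u), 1e-12)
  av <- pmax(abs(v), 1e-12)
  inside <- (au / a)^2 + (av / b)^2 < 1
  # F(t) = (a*au/(t+a^2))^2 + (b*av/(t+b^2))^2 - 1, strictly decreasing on
  # (-min(a,b)^2, Inf) with a unique root t*
  lo <- rep(-min(a, b)^2 + 1e-12, length(au))
  r <- sqrt(au^2 + av^2)
  hi <- pmax(a, b) * (r + pmax(a, b))
  Ff <- function(t) (a * au / (t + a^2))^2 + (b * av / (t + b^2))^2 - 1
  while (any(Ff(hi) > 0)) hi <- hi * 2
  for (i in seq_len(100L)) {
    mid <- 0.5 * (lo + hi)
    pos <- Ff(mid) > 0
    lo[pos] <- mid[pos]
    hi[!pos] <- mid[!pos]
  }
  t_star <- 0.5 * (lo + hi)
  xb <- a^2 * au / (t_star + a^2)
  yb <- b^2 * av / (t_star + b^2)
  d <- sqrt((au - xb)^2 + (av - yb)^2)
  ifelse(inside, -d, d) * 1  # sign convention: negative inside
}

#' Maximum cortical breach of a screw outside its pedicle corridor
#'
#' Samples the screw shaft surface (a finite cylinder from head to tip, tip
#' taper ignored) at `n_axial` stations along the axis and `n_angular`
#' points around the circumference, keeps the samples whose axial coordinate
#' falls inside the corridor extent, and returns the maximum signed distance
#' outside the corridor boundary. Negative values mean the screw is fully
#' contained (the value is minus the minimal clearance). Angular stations
#' are phase-staggered across axial stations (golden-ratio offsets) so the
#' default density resolves the true maximum to well under 0.01 mm.
#'
#' @param scr A one-row screw table.
#' @param corridor A `pedicle_corridor` in the same frame.
#' @param n_axial,n_angular Sampling densities (defaults 100 x 36).
#' @return Signed breach depth in mm.
#' @export
breach_depth <- function(scr, corridor, n_axial = 100L, n_angular = 36L) {
  stopifnot(is.data.frame(scr), nrow(scr) == 1L,
            inherits(corridor, "pedicle_corridor"))
  if (!identical(scr$frame, corridor$frame)) {
    stop_frame_error(sprintf("screw is in frame '%s' but corridor in '%s'",
                             scr$frame, corridor$frame))
  }
  h <- c(scr$head_x, scr$head_y, scr$head_z)
  tp <- c(scr$tip_x, scr$tip_y, scr$tip_z)
  axis_s <- tp - h
  L <- sqrt(sum(axis_s^2))
  axis_s <- axis_s / L
  r <- scr$diameter_mm / 2

  ew <- corridor$axis_dir
  eu <- corridor$ref_dir - sum(corridor$ref_dir * ew) * ew
  # transverse axis completes the corridor frame; sagittal = ref projection
  ev <- eu / sqrt(sum(eu^2))               # sagittal direction
  eu <- c(ev[2] * ew[3] - ev[3] * ew[2],   # transverse = sagittal x axis
          ev[3] * ew[1] - ev[1] * ew[3],
          ev[1] * ew[2] - ev[2] * ew[1])

  # circle basis derived from the corridor frame (not a fixed world axis) so
  # the sample point set is equivariant under common rigid transforms
  b1 <- eu - sum(eu * axis_s) * axis_s
  if (sqrt(sum(b1^2)) < 1e-8) b1 <- ev - sum(ev * axis_s) * axis_s
  b1 <- b1 / sqrt(sum(b1^2))
  b2 <- c(axis_s[2] * b1[3] - axis_s[3] * b1[2],
          axis_s[3] * b1[1] - axis_s[1] * b1[3],
          axis_s[1] * b1[2] - axis_s[2] * b1[1])

  s_frac <- (seq_len(n_axial) - 0.5) / n_axial
  centers <- outer(s_frac * L, axis_s) + rep(h, each = n_axial)
  phi <- ((seq_len(n_axial) * 0.618033988749895) %% 1) / n_angular
  theta <- outer(phi, (seq_len(n_angular) - 1) / n_angular, "+") * 2 * pi
  ct <- cos(theta); st <- sin(theta)                    # n_axial x n_angular
  px <- centers[, 1] + r * (ct * b1[1] + st * b2[1])
  py <- centers[, 2] + r * (ct * b1[2] + st * b2[2])
  pz <- centers[, 3] + r * (ct * b1[3] + st * b2[3])
  dx <- px - corridor$axis_point[1]
  dy <- py - corridor$axis_point[2]
  dz <- pz - corridor$axis_point[3]
  w <- dx * ew[1] + dy * ew[2] + dz * ew[3]
  keep <- w >= corridor$axial_extent_mm[1] & w <= corridor$axial_extent_mm[2]
  if (!any(keep)) {
    stop_navscrew(
      sprintf("screw %s/%s does not overlap the corridor's axial extent",
              scr$case_id, scr$screw_id),
      "navscrew_overlap_error"
    )
  }
  u <- (dx * eu[1] + dy * eu[2] + dz * eu[3])[keep]
  v <- (dx * ev[1] + dy * ev[2] + dz * ev[3])[keep]
  max(ellipse_signed_distance(u, v, corridor$semi_axis_transverse_mm,
                              corridor$semi_axis_sagittal_mm))
}

#' Gertzbein-Robbins grade from a breach depth
#'
#' Boundaries: breach <= 0 is grade A; (0, 2) B; [2, 4) C; [4, 6) D; >= 6 E.
#' Grades A and B are clinically acceptable.
#'
#' @param breach_mm Signed breach depth(s) in mm (finite).
#' @return Data.frame with `grade` (factor A-E), `breach_mm`, `acceptable`.
#' @export
grade_from_breach <- function(breach_mm) {
  stopifnot(all(is.finite(breach_mm)))
  grade <- cut(breach_mm, breaks = c(-Inf, 0, 2, 4, 6, Inf),
               labels = c("A", "B", "C", "D", "E"),
               right = FALSE, include.lowest = TRUE)
  # cut() with right = FALSE puts 0 into B; grade A must include breach == 0
  grade[breach_mm <= 0] <- "A"
  data.frame(grade = factor(grade, levels = c("A", "B", "C", "D", "E")),
             breach_mm = breach_mm,
             acceptable = grade %in% c("A", "B"))
}

#' Grade one screw against its corridor
#'
#' @inheritParams breach_depth
#' @return One-row data.frame as in [grade_from_breach()].
#' @export
grade_screw <- function(scr, corridor, n_axial = 100L, n_angular = 36L) {
  grade_from_breach(breach_depth(scr, corridor, n_axial, n_angular))
}

# ---- corridor tables --------------------------------------------------------

CORRIDOR_COLUMNS <- c("case_id", "level", "side", "axis_x", "axis_y", "axis_z",
                      "dir_x", "dir_y", "dir_z", "ref_x", "ref_y", "ref_z",
                      "semi_transverse_mm", "semi_sagittal_mm",
                      "extent_start_mm", "extent_end_mm", "frame")

#' Convert between corridor objects and a corridor table
#'
#' Corridor tables hold one corridor per row (keyed by case, level, side)
#' and are the on-disk CSV format.
#'
#' @param corridors List of `pedicle_corridor` objects, or a data.frame in
#'   the corridor-table schema.
#' @return `corridor_table()` returns a data.frame; `corridor_from_row()`
#'   a `pedicle_corridor`.
#' @export
corridor_table <- function(corridors) {
  rows <- lapply(corridors, function(cc) {
    data.frame(case_id = cc$case_id, level = cc$level, side = cc$side,
               axis_x = cc$axis_point[1], axis_y = cc$axis_point[2],
               axis_z = cc$axis_point[3],
               dir_x = cc$axis_dir[1], dir_y = cc$axis_dir[2],
               dir_z = cc$axis_dir[3],
               ref_x = cc$ref_dir[1], ref_y = cc$ref_dir[2], ref_z = cc$ref_dir[3],
               semi_transverse_mm = cc$semi_axis_transverse_mm,
               semi_sagittal_mm = cc$semi_axis_sagittal_mm,
               extent_start_mm = cc$axial_extent_mm[1],
               extent_end_mm = cc$axial_extent_mm[2],
               frame = cc$frame, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @rdname corridor_table
#' @param row One row of a corridor table.
#' @export
corridor_from_row <- function(row) {
  pedicle_corridor(
    level = row$level,
    axis_point = c(row$axis_x, row$axis_y, row$axis_z),
    axis_dir = c(row$dir_x, row$dir_y, row$dir_z),
    semi_axis_transverse_mm = row$semi_transverse_mm,
    semi_axis_sagittal_mm = row$semi_sagittal_mm,
    axial_extent_mm = c(row$extent_start_mm, row$extent_end_mm),
    frame = row$frame, ref_dir = c(row$ref_x, row$ref_y, row$ref_z),
    case_id = row$case_id, side = row$side
  )
}

#' Grade a screw table against a corridor table
#'
#' Matches corridors to screws by `(case_id, level, side)` and grades each
#' screw. Corridors must already be in the screws' frame (map them with
#' [transform_corridor()] first when needed).
#'
#' @param screws Screw table.
#' @param corridors Corridor table (data.frame).
#' @param n_axial,n_angular Sampling densities.
#' @return The grade table: screw identifiers plus `breach_mm`, `grade`,
#'   `acceptable`.
#' @export
grade_screws <- function(screws, corridors, n_axial = 100L, n_angular = 36L) {
  key_c <- paste(corridors$case_id, corridors$level, corridors$side)
  key_s <- paste(screws$case_id, screws$level, screws$side)
  idx <- match(key_s, key_c)
  if (anyNA(idx)) {
    stop_navscrew(sprintf("no corridor for screw(s): %s",
                          paste(screws$screw_id[is.na(idx)], collapse = ", ")),
                  "navscrew_pairing_error")
  }
  breach <- vapply(seq_len(nrow(screws)), function(i) {
    breach_depth(screws[i, , drop = FALSE], corridor_from_row(corridors[idx[i], ]),
                 n_axial, n_angular)
  }, numeric(1))
  g <- grade_from_breach(breach)
  cbind(screws[, c("case_id", "screw_id", "level", "side")], g)
}
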