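# Planned-versus-actual deviation metrics: per-screw Euclidean head/tip
# point distances (MAD), angular trajectory deviation, and dimension
# differences, plus the per-level aggregation with a minimum-n exclusion
# rule for under-represented levels.

#' Pair planned and final screws
#'
#' Matches screws 1:1 on `(case_id, screw_id)` and returns the two tables
#' aligned row-for-row, ordered deterministically by case, level (L1-S1) and
#' side. Unmatched or duplicated keys raise a pairing error naming the
#' offending screws.
#'
#' @param plans Screw table with `role == "planned"`.
#' @param finals Screw table with `role == "final"`.
#' @return List with elements `plan` and `final`: aligned screw tables.
#' @export
pair_screws <- function(plans, finals) {
  if (nrow(plans) && !all(plans$role == "planned")) {
    stop_navscrew("`plans` must contain only planned screws", "navscrew_pairing_error")
  }
  if (nrow(finals) && !all(finals$role == "final")) {
    stop_navscrew("`finals` must contain only final screws", "navscrew_pairing_error")
  }
  kp <- paste(plans$case_id, plans$screw_id, sep = "\r")
  kf <- paste(finals$case_id, finals$screw_id, sep = "\r")
  dup <- c(kp[duplicated(kp)], kf[duplicated(kf)])
  if (length(dup)) {
    stop_navscrew(sprintf("duplicated screw key(s): %s",
                          paste(unique(gsub("\r", "/", dup)), collapse = ", ")),
                  "navscrew_pairing_error")
  }
  only_p <- setdiff(kp, kf)
  only_f <- setdiff(kf, kp)
  if (length(only_p) || length(only_f)) {
    stop_navscrew(sprintf(
      "unpaired screws: %s%s",
      if (length(only_p)) paste0("planned without final: ",
                                 paste(gsub("\r", "/", only_p), collapse = ", ")) else "",
      if (length(only_f)) paste0(if (length(only_p)) "; " else "",
                                 "final without planned: ",
                                 paste(gsub("\r", "/", only_f), collapse = ", ")) else ""
    ), "navscrew_pairing_error")
  }
  ord <- order(plans$case_id, match(plans$level, SPINAL_LEVELS), plans$side)
  plans <- plans[ord, , drop = FALSE]
  finals <- finals[match(paste(plans$case_id, plans$screw_id, sep = "\r"), kf), ,
                   drop = FALSE]
  mism <- which(plans$level != finals$level | plans$side != finals$side)
  if (length(mism)) {
    stop_navscrew(sprintf("level/side mismatch within pair(s): %s",
                          paste(plans$screw_id[mism], collapse = ", ")),
                  "navscrew_pairing_error")
  }
  rownames(plans) <- rownames(finals) <- NULL
  list(plan = plans, final = finals)
}

#' Per-screw planned-versus-final deviation metrics
#'
#' Maps the planned screws into the final screws' frame via `frame_map` (or
#' requires a shared frame when `NULL`), then computes for each pair the
#' Euclidean head and tip point distances (MAD, mm), the angle between the
#' head-to-tip axes (degrees), and the final-minus-planned length and
#' diameter differences. Angles above 90 degrees are reported unfolded and
#' flagged with a warning, since planned and final screws are never
#' antiparallel in practice.
#'
#' @param plan,final Aligned screw tables (see [pair_screws()]); for
#'   convenience single screws (one-row tables) work too.
#' @param frame_map Optional `rigid_transform` from the planned frame onto
#'   the final frame; `NULL` requires both tables in one frame already.
#' @return A deviation table: one row per screw with `case_id`, `screw_id`,
#'   `level`, `side`, `mad_head_mm`, `mad_tip_mm`, `angle_deg`,
#'   `dlength_mm`, `ddiameter_mm`, and the planned/final dimensions.
#' @export
compare_screws <- function(plan, final, frame_map = NULL) {
  if (nrow(plan) != nrow(final) ||
      any(plan$case_id != final$case_id) || any(plan$screw_id != final$screw_id)) {
    stop_navscrew("plan and final tables are not aligned; use pair_screws()",
                  "navscrew_pairing_error")
  }
  if (!is.null(frame_map)) {
    plan <- transform_screws(frame_map, plan)
  }
  fp <- unique(plan$frame)
  ff <- unique(final$frame)
  if (length(fp) != 1L || length(ff) != 1L || !identical(fp, ff)) {
    stop_frame_error(sprintf(
      "planned screws are in frame '%s' but final screws in '%s'; supply `frame_map`",
      paste(fp, collapse = ","), paste(ff, collapse = ",")
    ))
  }
  angle <- angle_between_deg(axis_of(plan), axis_of(final))
  if (any(angle > 90)) {
    warning(sprintf("%d screw pair(s) with axis deviation > 90 degrees (anomalous)",
                    sum(angle > 90)))
  }
  out <- data.frame(
    case_id = plan$case_id, screw_id = plan$screw_id,
    level = plan$level, side = plan$side,
    mad_head_mm = euclidean_mad(screw_heads(plan), screw_heads(final)),
    mad_tip_mm = euclidean_mad(screw_tips(plan), screw_tips(final)),
    angle_deg = angle,
    dlength_mm = final$length_mm - plan$length_mm,
    ddiameter_mm = final$diameter_mm - plan$diameter_mm,
    length_planned_mm = plan$length_mm, length_final_mm = final$length_mm,
    diameter_planned_mm = plan$diameter_mm, diameter_final_mm = final$diameter_mm,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

DEVIATION_METRICS <- c("mad_head_mm", "mad_tip_mm", "angle_deg")

#' Per-level summaries of deviation metrics
#'
#' One summary row per spinal level present and metric: n, mean, sample SD
#' (n-1 denominator; `NA` for n = 1), min and max. Levels with fewer than
#' `min_n` screws are still summarized but flagged `excluded_from_stats`, so
#' sparse levels do not enter inferential comparisons.
#'
#' @param devs A deviation table from [compare_screws()].
#' @param min_n Minimum screws per level for inclusion in statistics
#'   (default 3).
#' @param metrics Metric columns to summarize.
#' @return List with `by_level` (data.frame of summaries) and
#'   `excluded_levels` (character).
#' @export
summarize_by_level <- function(devs, min_n = 3,
                               metrics = DEVIATION_METRICS) {
  stopifnot(nrow(devs) > 0L)
  levels_present <- intersect(SPINAL_LEVELS, unique(devs$level))
  rows <- list()
  for (lv in levels_present) {
    sub <- devs[devs$level == lv, , drop = FALSE]
    for (m in metrics) {
      v <- sub[[m]]
      rows[[length(rows) + 1L]] <- data.frame(
        level = lv, metric = m, n = length(v),
        mean = mean(v), sd = if (length(v) >= 2L) stats::sd(v) else NA_real_,
        min = min(v), max = max(v),
        excluded_from_stats = length(v) < min_n,
        stringsAsFactors = FALSE
      )
    }
  }
  by_level <- do.call(rbind, rows)
  rownames(by_level) <- NULL
  excluded <- unique(by_level$level[by_level$excluded_from_stats])
  list(by_level = by_level, excluded_levels = excluded)
}

#' Compare planned and final screw dimensions by their means
#'
#' @param devs A deviation table from [compare_screws()].
#' @return Data.frame with one row per dimension (length, diameter): mean
#'   planned, mean final, mean difference (final - planned) and mean
#'   absolute difference, all in mm.
#' @export
compare_dimensions <- function(devs) {
  stopifnot(nrow(devs) > 0L)
  data.frame(
    dimension = c("length_mm", "diameter_mm"),
    mean_planned = c(mean(devs$length_planned_mm), mean(devs$diameter_planned_mm)),
    mean_final = c(mean(devs$length_final_mm), mean(devs$diameter_final_mm)),
    mean_diff = c(mean(devs$dlength_mm), mean(devs$ddiameter_mm)),
    mean_abs_diff = c(mean(abs(devs$dlength_mm)), mean(abs(devs$ddiameter_mm))),
    stringsAsFactors = FALSE
  )
}
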