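# Orchestration: read inputs (or simulate), co-register and verify each
# case, exclude cases with inaccurate co-registration, pair and compare
# screws, grade them, summarize per level and per grade, and run the
# statistical battery. The report mirrors the conventional result structure
# of navigated-accuracy studies: cohort composition, overall and per-level
# deviation summaries, grade distribution with per-grade comparisons, and
# the deviation-versus-registration-error test.

#' Pipeline configuration
#'
#' Exactly one input mode: pass a `synthetic_cohort` (or a
#' `simulation_config` to simulate one), or file paths to a screw table,
#' landmark table and corridor table in the documented CSV schemas.
#'
#' @param cohort A `synthetic_cohort`, or `NULL` in file mode.
#' @param simulate A `simulation_config` to generate the cohort from, or
#'   `NULL`.
#' @param screws,landmarks,corridors File paths (file mode).
#' @param tau_mm Per-level co-registration verification threshold (mm).
#' @param min_n Minimum screws per level for inclusion in per-level
#'   statistics.
#' @param grade Run the Gertzbein-Robbins grading stage (can be disabled
#'   for speed in large simulation studies).
#' @param include_angle_vs_tre Include the angle group in the
#'   deviation-versus-registration-error comparison (units mismatch; off by
#'   default).
#' @param aggregate_tre_per_case Aggregate deviations per case before the
#'   registration-error comparison instead of mixing per-screw deviations
#'   with per-case errors (off by default, replicating conventional
#'   reporting; the mixing is logged).
#' @param output_dir If non-NULL, [render_report()] is called on the result.
#' @return A `pipeline_config`.
#' @export
pipeline_config <- function(cohort = NULL, simulate = NULL,
                            screws = NULL, landmarks = NULL, corridors = NULL,
                            tau_mm = 2, min_n = 3, grade = TRUE,
                            include_angle_vs_tre = FALSE,
                            aggregate_tre_per_case = FALSE,
                            output_dir = NULL) {
  file_mode <- !is.null(screws)
  obj_mode <- !is.null(cohort) || !is.null(simulate)
  if (file_mode == obj_mode) {
    stop_navscrew("exactly one input mode: files (screws/landmarks/corridors) xor cohort/simulate",
                  "navscrew_config_error")
  }
  if (file_mode) {
    for (p in c(screws, landmarks, corridors)) {
      if (!file.exists(p)) {
        stop_navscrew(sprintf("input file not found: %s", p), "navscrew_config_error")
      }
    }
  }
  structure(
    list(cohort = cohort, simulate = simulate, screws = screws,
         landmarks = landmarks, corridors = corridors, tau_mm = tau_mm,
         min_n = min_n, grade = grade,
         include_angle_vs_tre = include_angle_vs_tre,
         aggregate_tre_per_case = aggregate_tre_per_case,
         output_dir = output_dir),
    class = "pipeline_config"
  )
}

#' Read a screw table from CSV or JSON
#'
#' Validates the documented schema (see [screw_table()]) and reports the
#' offending row and field on failure.
#'
#' @param path CSV (header, comma, decimal point) or JSON array of row
#'   objects.
#' @return A validated screw table.
#' @export
read_screw_table <- function(path) {
  df <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE),
                  stringsAsFactors = FALSE)
  } else {
    utils::read.csv(path, stringsAsFactors = FALSE)
  }
  screw_table(df)
}

#' Write a screw table to CSV
#' @param s Screw table.
#' @param path Output path.
#' @export
write_screw_table <- function(s, path) {
  utils::write.csv(screw_table(s), path, row.names = FALSE)
  invisible(path)
}

#' Run the full planned-versus-actual analysis pipeline
#'
#' Stages: per-case rigid co-registration from verification landmarks,
#' per-level verification against `tau_mm` with case-level exclusion,
#' per-case navigation registration error from reference-screw fiducials,
#' screw pairing and deviation computation in the control frame, grading
#' against the pedicle corridors, per-level and per-grade summaries, and
#' the statistical battery. Deterministic given its inputs.
#'
#' @param cfg A [pipeline_config()].
#' @return A `study_report` (list; see Details) with per-screw tables
#'   backing every reported summary.
#' @details Report components: `cohort` (cases/screw counts per level),
#'   `exclusions` (case ids, flagged levels, residuals), `deviations`
#'   (per-screw table with grades), `overall` (mean/SD/range per metric),
#'   `by_level` + `excluded_levels`, `dimensions`, `grades` (distribution),
#'   `per_level_tests`, `grade_group_tests`, `grade_by_level_test`,
#'   `covariate_tests`, `deviation_vs_tre`, `tre_by_case`, `verdicts`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  if (!is.null(cfg$simulate)) {
    cohort <- simulate_cohort(cfg$simulate)
  } else if (!is.null(cfg$cohort)) {
    cohort <- cfg$cohort
  } else {
    cohort <- list(
      screws = read_screw_table(cfg$screws),
      landmarks = read_landmarks(cfg$landmarks),
      corridors = utils::read.csv(cfg$corridors, stringsAsFactors = FALSE),
      covariates = NULL
    )
  }
  screws <- cohort$screws
  landmarks <- cohort$landmarks
  if (!"set" %in% names(landmarks)) landmarks$set <- "coreg"
  case_ids <- unique(screws$case_id)

  # ---- stage: co-registration + verification --------------------------------
  verdicts <- list()
  coreg_fits <- list()
  for (cid in case_ids) {
    lm_df <- landmarks[landmarks$case_id == cid & landmarks$set == "coreg", ]
    if (nrow(lm_df) == 0L) {
      stop_navscrew(sprintf("[coregister] no verification landmarks for case %s", cid),
                    "navscrew_validation_error")
    }
    fit <- fit_rigid_landmarks(landmark_set(
      source = as.matrix(lm_df[, c("src_x", "src_y", "src_z")]),
      target = as.matrix(lm_df[, c("dst_x", "dst_y", "dst_z")]),
      source_frame = "navCT", target_frame = "controlCT",
      labels = lm_df$label, level = lm_df$level
    ))
    coreg_fits[[cid]] <- fit
    verdicts[[cid]] <- verify_coregistration(per_level_residuals(fit), cfg$tau_mm)
  }
  excluded_cases <- case_ids[vapply(verdicts, function(v) v$case_excluded, logical(1))]
  exclusions <- data.frame(
    case_id = excluded_cases,
    flagged_levels = vapply(excluded_cases, function(cid) {
      paste(verdicts[[cid]]$flagged_levels, collapse = "+")
    }, character(1)),
    max_residual_mm = vapply(excluded_cases, function(cid) {
      max(verdicts[[cid]]$per_level_residual_mm)
    }, numeric(1)),
    stringsAsFactors = FALSE
  )
  included <- setdiff(case_ids, excluded_cases)
  if (length(excluded_cases)) {
    message(sprintf("[verify] excluded %d case(s) for inaccurate co-registration: %s",
                    length(excluded_cases), paste(excluded_cases, collapse = ", ")))
  }
  if (!length(included)) {
    stop_navscrew("[verify] all cases excluded; nothing to analyze",
                  "navscrew_validation_error")
  }

  # ---- stage: navigation registration error ---------------------------------
  tre_by_case <- stats::setNames(rep(NA_real_, length(included)), included)
  for (cid in included) {
    f <- landmarks[landmarks$case_id == cid & landmarks$set == "patient_fiducial", ]
    tg <- landmarks[landmarks$case_id == cid & landmarks$set == "tre_target", ]
    if (nrow(f) >= 3L && nrow(tg) >= 1L) {
      r <- fit_rigid_landmarks(landmark_set(
        source = as.matrix(f[, c("src_x", "src_y", "src_z")]),
        target = as.matrix(f[, c("dst_x", "dst_y", "dst_z")]),
        source_frame = "patient", target_frame = "navCT", labels = f$label
      ))
      tre_by_case[cid] <- target_registration_error(
        r, as.matrix(tg[, c("src_x", "src_y", "src_z")]),
        as.matrix(tg[, c("dst_x", "dst_y", "dst_z")])
      )
    }
  }

  # ---- stage: pair + compare ------------------------------------------------
  keep <- screws$case_id %in% included
  pairs <- pair_screws(screws[keep & screws$role == "planned", , drop = FALSE],
                       screws[keep & screws$role == "final", , drop = FALSE])
  devs_list <- lapply(included, function(cid) {
    pi_ <- pairs$plan$case_id == cid
    compare_screws(pairs$plan[pi_, , drop = FALSE],
                   pairs$final[pi_, , drop = FALSE],
                   frame_map = coreg_fits[[cid]]$transform)
  })
  devs <- do.call(rbind, devs_list)
  rownames(devs) <- NULL

  # ---- stage: grade ---------------------------------------------------------
  grades <- NULL
  if (isTRUE(cfg$grade) && !is.null(cohort$corridors)) {
    finals <- pairs$final
    grade_list <- lapply(included, function(cid) {
      cc <- cohort$corridors[cohort$corridors$case_id == cid, , drop = FALSE]
      fits <- coreg_fits[[cid]]$transform
      cc_ctrl <- do.call(rbind, lapply(seq_len(nrow(cc)), function(i) {
        corridor_table(list(transform_corridor(fits, corridor_from_row(cc[i, ]))))
      }))
      grade_screws(finals[finals$case_id == cid, , drop = FALSE], cc_ctrl)
    })
    grades <- do.call(rbind, grade_list)
    rownames(grades) <- NULL
    devs <- merge(devs, grades[, c("case_id", "screw_id", "breach_mm", "grade",
                                   "acceptable")],
                  by = c("case_id", "screw_id"), sort = FALSE)
    devs <- devs[order(devs$case_id, match(devs$level, SPINAL_LEVELS), devs$side), ]
    rownames(devs) <- NULL
  }

  # ---- stage: summarize -----------------------------------------------------
  overall <- data.frame(
    metric = DEVIATION_METRICS,
    n = nrow(devs),
    mean = vapply(DEVIATION_METRICS, function(m) mean(devs[[m]]), numeric(1)),
    sd = vapply(DEVIATION_METRICS, function(m) stats::sd(devs[[m]]), numeric(1)),
    min = vapply(DEVIATION_METRICS, function(m) min(devs[[m]]), numeric(1)),
    max = vapply(DEVIATION_METRICS, function(m) max(devs[[m]]), numeric(1)),
    stringsAsFactors = FALSE
  )
  lvl <- summarize_by_level(devs, min_n = cfg$min_n)
  dims <- compare_dimensions(devs)
  cohort_summary <- list(
    n_cases_input = length(case_ids),
    n_cases_analyzed = length(included),
    n_cases_excluded = length(excluded_cases),
    n_screws_input = sum(screws$role == "final"),
    n_screws_analyzed = nrow(devs),
    screws_per_level = table(factor(devs$level, levels = SPINAL_LEVELS))
  )

  # ---- stage: statistics ----------------------------------------------------
  eligible <- setdiff(unique(devs$level), lvl$excluded_levels)
  per_level_tests <- list()
  for (m in DEVIATION_METRICS) {
    groups <- lapply(eligible, function(lv) devs[[m]][devs$level == lv])
    names(groups) <- eligible
    if (length(groups) >= 2L && all(vapply(groups, length, integer(1)) >= 2L)) {
      av <- one_way_anova(groups)
      others <- setdiff(eligible, "S1")
      post <- NULL
      if ("S1" %in% eligible && length(others)) {
        praw <- vapply(others, function(lv) {
          two_sample_t(devs[[m]][devs$level == lv], devs[[m]][devs$level == "S1"])$p_value
        }, numeric(1))
        post <- holm_sidak_adjust(praw, labels = paste(others, "vs S1"))
      }
      per_level_tests[[m]] <- list(anova = av, posthoc_vs_S1 = post)
    }
  }

  grade_group_tests <- NULL
  grade_by_level_test <- NULL
  covariate_tests <- NULL
  if (!is.null(grades)) {
    gA <- devs$grade == "A"
    if (sum(gA) >= 2L && sum(!gA) >= 2L) {
      grade_group_tests <- lapply(
        stats::setNames(DEVIATION_METRICS, DEVIATION_METRICS),
        function(m) two_sample_t(devs[[m]][gA], devs[[m]][!gA])
      )
      tre_of_screw <- tre_by_case[devs$case_id]
      if (!anyNA(tre_of_screw)) {
        grade_group_tests$tre_mm <- two_sample_t(tre_of_screw[gA], tre_of_screw[!gA])
      }
    }
    tab <- table(devs$level, devs$acceptable)
    tab <- tab[rowSums(tab) > 0, , drop = FALSE]
    if (nrow(tab) >= 2L && ncol(tab) >= 2L && all(colSums(tab) > 0)) {
      grade_by_level_test <- chi_square_test(tab)
    }
    if (!is.null(cohort$covariates)) {
      cov <- cohort$covariates[cohort$covariates$case_id %in% included, ]
      case_grade <- tapply(devs$acceptable, devs$case_id, all)
      grp <- ifelse(case_grade[cov$case_id], "all_grade_A", "any_grade_B_or_worse")
      if (length(unique(grp)) == 2L && min(table(grp)) >= 2L) {
        covariate_tests <- lapply(
          stats::setNames(c("age", "weight_kg", "bmi"), c("age", "weight_kg", "bmi")),
          function(v) kruskal_wallis(split(cov[[v]], grp))
        )
      }
    }
  }

  dev_vs_tre <- NULL
  tre_ok <- tre_by_case[!is.na(tre_by_case)]
  if (length(tre_ok) >= 2L && all(unique(devs$case_id) %in% names(tre_ok))) {
    dev_vs_tre <- tryCatch(
      deviations_vs_registration_error(
        devs, tre_ok, include_angle = cfg$include_angle_vs_tre,
        aggregate_per_case = cfg$aggregate_tre_per_case
      ),
      navscrew_degenerate_error = function(e) {
        message("[stats] deviation-vs-registration-error comparison skipped: ",
                conditionMessage(e))
        NULL
      }
    )
    if (!cfg$aggregate_tre_per_case) {
      message("[stats] comparing per-screw deviations with per-case registration errors (mixed analysis units)")
    }
  }

  report <- structure(
    list(cohort = cohort_summary, exclusions = exclusions, verdicts = verdicts,
         deviations = devs, overall = overall, by_level = lvl$by_level,
         excluded_levels = lvl$excluded_levels, dimensions = dims,
         grades = if (!is.null(grades)) table(factor(devs$grade, levels = c("A", "B", "C", "D", "E"))) else NULL,
         per_level_tests = per_level_tests,
         grade_group_tests = grade_group_tests,
         grade_by_level_test = grade_by_level_test,
         covariate_tests = covariate_tests,
         deviation_vs_tre = dev_vs_tre,
         tre_by_case = tre_by_case,
         config = cfg),
    class = "study_report"
  )
  if (!is.null(cfg$output_dir)) render_report(report, cfg$output_dir)
  report
}

#' @export
print.study_report <- function(x, ...) {
  cat("== planned-versus-actual screw accuracy report ==\n")
  cat(sprintf("cases: %d analyzed / %d input (%d excluded); screws: %d\n",
              x$cohort$n_cases_analyzed, x$cohort$n_cases_input,
              x$cohort$n_cases_excluded, x$cohort$n_screws_analyzed))
  ov <- x$overall
  for (i in seq_len(nrow(ov))) {
    unit <- if (ov$metric[i] == "angle_deg") "deg" else "mm"
    cat(sprintf("  %-12s %5.2f +/- %4.2f %s (range %.2f-%.2f)\n",
                ov$metric[i], ov$mean[i], ov$sd[i], unit, ov$min[i], ov$max[i]))
  }
  tre <- x$tre_by_case[!is.na(x$tre_by_case)]
  if (length(tre)) {
    cat(sprintf("  registration error: %.2f +/- %.2f mm (n=%d cases)\n",
                mean(tre), stats::sd(tre), length(tre)))
  }
  if (!is.null(x$grades)) {
    cat("  grades:", paste(sprintf("%s=%d", names(x$grades), x$grades), collapse = " "), "\n")
  }
  invisible(x)
}

#' Render a study report to CSV files and a markdown summary
#'
#' Writes `deviations.csv` (per-screw table backing every summary),
#' `by_level.csv`, `overall.csv`, `dimensions.csv`, `tre_by_case.csv`,
#' `grade_distribution.csv` (when graded), a long-format
#' `deviation_long.csv` ready for violin-style plotting, and `report.md`.
#'
#' @param report A `study_report`.
#' @param dir Output directory.
#' @param format Currently `"markdown"`.
#' @return `dir`, invisibly.
#' @export
render_report <- function(report, dir, format = "markdown") {
  stopifnot(inherits(report, "study_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, f) utils::write.csv(df, file.path(dir, f), row.names = FALSE)
  w(report$deviations, "deviations.csv")
  w(report$overall, "overall.csv")
  w(report$by_level, "by_level.csv")
  w(report$dimensions, "dimensions.csv")
  w(data.frame(case_id = names(report$tre_by_case),
               tre_mm = as.numeric(report$tre_by_case)), "tre_by_case.csv")
  long <- do.call(rbind, lapply(DEVIATION_METRICS, function(m) {
    data.frame(case_id = report$deviations$case_id,
               screw_id = report$deviations$screw_id,
               level = report$deviations$level, metric = m,
               value = report$deviations[[m]], stringsAsFactors = FALSE)
  }))
  w(long, "deviation_long.csv")
  if (!is.null(report$grades)) {
    w(data.frame(grade = names(report$grades), n = as.integer(report$grades)),
      "grade_distribution.csv")
  }

  md <- c("# Planned-versus-actual screw accuracy report", "")
  md <- c(md, "## Cohort", "",
          sprintf("- cases analyzed: %d of %d (%d excluded)",
                  report$cohort$n_cases_analyzed, report$cohort$n_cases_input,
                  report$cohort$n_cases_excluded),
          sprintf("- screws analyzed: %d of %d",
                  report$cohort$n_screws_analyzed, report$cohort$n_screws_input),
          sprintf("- screws per level: %s",
                  paste(sprintf("%s=%d", names(report$cohort$screws_per_level),
                                report$cohort$screws_per_level), collapse = ", ")),
          "")
  md <- c(md, "## Excluded cases", "")
  if (nrow(report$exclusions)) {
    md <- c(md, sprintf("- %s: flagged %s (max residual %.2f mm)",
                        report$exclusions$case_id, report$exclusions$flagged_levels,
                        report$exclusions$max_residual_mm), "")
  } else {
    md <- c(md, "")
  }
  md <- c(md, "## Overall deviations", "",
          "| metric | n | mean | SD | min | max |",
          "|---|---|---|---|---|---|",
          sprintf("| %s | %d | %.2f | %.2f | %.2f | %.2f |",
                  report$overall$metric, report$overall$n, report$overall$mean,
                  report$overall$sd, report$overall$min, report$overall$max),
          "")
  tre <- report$tre_by_case[!is.na(report$tre_by_case)]
  if (length(tre)) {
    md <- c(md, sprintf("Navigation registration error: %.2f +/- %.2f mm (range %.2f-%.2f, n=%d cases).",
                        mean(tre), stats::sd(tre), min(tre), max(tre), length(tre)), "")
  }
  md <- c(md, "## Per-level deviations", "",
          "| level | metric | n | mean | SD | excluded from stats |",
          "|---|---|---|---|---|---|",
          sprintf("| %s | %s | %d | %.2f | %s | %s |",
                  report$by_level$level, report$by_level$metric, report$by_level$n,
                  report$by_level$mean,
                  ifelse(is.na(report$by_level$sd), "-", sprintf("%.2f", report$by_level$sd)),
                  ifelse(report$by_level$excluded_from_stats, "yes", "")),
          "")
  if (!is.null(report$grades)) {
    md <- c(md, "## Gertzbein-Robbins distribution", "",
            paste(sprintf("%s: %d", names(report$grades), report$grades),
                  collapse = "; "), "")
  }
  if (!is.null(report$deviation_vs_tre)) {
    ph <- report$deviation_vs_tre$posthoc
    md <- c(md, "## Deviation versus registration error", "",
            sprintf("ANOVA F = %.2f, p = %.3g.",
                    report$deviation_vs_tre$anova$statistic,
                    report$deviation_vs_tre$anova$p_value),
            "",
            sprintf("- %s: adjusted p = %.3g", ph$comparison, ph$p_adjusted), "")
    w(ph, "deviation_vs_tre.csv")
  }
  writeLines(md, file.path(dir, "report.md"))
  invisible(dir)
}
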