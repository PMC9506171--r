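# Statistical battery for the accuracy analysis: pooled/Welch two-sample t,
# one-way ANOVA, Holm-Sidak step-down adjustment, Pearson chi-square and
# Kruskal-Wallis, plus the deviation-versus-registration-error comparison.
# All tests are two-sided with alpha = 0.05 by convention; the
# implementations are self-contained so that base R's t.test/aov/chisq.test/
# kruskal.test can serve as independent cross-checks in the test suite.

#' @noRd
test_result <- function(statistic, df, p_value, method, group_summaries = NULL) {
  structure(
    list(statistic = statistic, df = df, p_value = p_value, method = method,
         group_summaries = group_summaries),
    class = "test_result"
  )
}

#' @export
print.test_result <- function(x, ...) {
  df_str <- paste(signif(x$df, 6), collapse = ", ")
  cat(sprintf("<%s: statistic %.4f, df %s, p %.4g>\n",
              x$method, x$statistic, df_str, x$p_value))
  if (!is.null(x$group_summaries)) print(x$group_summaries, digits = 4)
  invisible(x)
}

#' @noRd
summarize_groups <- function(groups) {
  data.frame(
    group = names(groups) %||% as.character(seq_along(groups)),
    n = vapply(groups, length, integer(1)),
    mean = vapply(groups, mean, numeric(1)),
    sd = vapply(groups, function(v) if (length(v) >= 2) stats::sd(v) else NA_real_,
                numeric(1)),
    stringsAsFactors = FALSE
  )
}

#' Two-sample t test (pooled or Welch)
#'
#' Two-sided. The pooled (Student) variant is the default; Welch's unequal
#' variance variant with Satterthwaite degrees of freedom is available via
#' `variant = "welch"`.
#'
#' @param x,y Numeric samples, each with at least 2 observations.
#' @param variant `"pooled"` or `"welch"`.
#' @return A `test_result`.
#' @export
two_sample_t <- function(x, y, variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  x <- as.numeric(x); y <- as.numeric(y)
  nx <- length(x); ny <- length(y)
  if (nx < 2L || ny < 2L) {
    stop_navscrew("each sample needs at least 2 observations",
                  "navscrew_degenerate_error")
  }
  vx <- stats::var(x); vy <- stats::var(y)
  if (variant == "pooled") {
    sp2 <- ((nx - 1) * vx + (ny - 1) * vy) / (nx + ny - 2)
    if (sp2 <= 0) {
      stop_navscrew("zero pooled variance: t statistic undefined",
                    "navscrew_degenerate_error")
    }
    se <- sqrt(sp2 * (1 / nx + 1 / ny))
    df <- nx + ny - 2
  } else {
    if (vx <= 0 && vy <= 0) {
      stop_navscrew("zero variance in both samples: t statistic undefined",
                    "navscrew_degenerate_error")
    }
    se <- sqrt(vx / nx + vy / ny)
    df <- (vx / nx + vy / ny)^2 /
      ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  }
  tstat <- (mean(x) - mean(y)) / se
  test_result(
    statistic = tstat, df = df,
    p_value = 2 * stats::pt(abs(tstat), df, lower.tail = FALSE),
    method = sprintf("two-sample t (%s)", variant),
    group_summaries = summarize_groups(list(x = x, y = y))
  )
}

#' One-way analysis of variance
#'
#' @param groups List of numeric samples (at least 2 groups, each with at
#'   least 2 observations).
#' @return A `test_result` with the F statistic and `(k-1, N-k)` degrees of
#'   freedom. When all values are identical, F = 0 and p = 1.
#' @export
one_way_anova <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L) {
    stop_navscrew("one_way_anova needs at least 2 groups", "navscrew_degenerate_error")
  }
  if (any(vapply(groups, length, integer(1)) < 2L)) {
    stop_navscrew("each group needs at least 2 observations",
                  "navscrew_degenerate_error")
  }
  k <- length(groups)
  n <- vapply(groups, length, integer(1))
  N <- sum(n)
  means <- vapply(groups, mean, numeric(1))
  grand <- sum(n * means) / N
  ssb <- sum(n * (means - grand)^2)
  ssw <- sum(vapply(groups, function(v) sum((v - mean(v))^2), numeric(1)))
  df1 <- k - 1L
  df2 <- N - k
  msw <- ssw / df2
  if (msw <= 0) {
    if (ssb <= 1e-24) {
      fstat <- 0; p <- 1
    } else {
      fstat <- Inf; p <- 0
    }
  } else {
    fstat <- (ssb / df1) / msw
    p <- stats::pf(fstat, df1, df2, lower.tail = FALSE)
  }
  test_result(fstat, c(df1, df2), p, "one-way ANOVA",
              group_summaries = summarize_groups(groups))
}

#' Holm-Sidak step-down adjustment
#'
#' Step-down procedure: p-values are sorted ascending and the i-th smallest
#' is adjusted to `1 - (1 - p)^(m - i + 1)`; a running maximum enforces
#' monotonicity and values are capped at 1. Results are returned in the
#' original order.
#'
#' @param p Numeric vector of raw p-values in `[0, 1]`.
#' @param labels Optional comparison labels.
#' @return A `posthoc_table` data.frame: `comparison`, `p_raw`, `p_adjusted`.
#' @export
holm_sidak_adjust <- function(p, labels = NULL) {
  p <- as.numeric(p)
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop_navscrew("p-values must lie in [0, 1]", "navscrew_validation_error")
  }
  m <- length(p)
  o <- order(p)
  adj_sorted <- 1 - (1 - p[o])^(m - seq_len(m) + 1)
  adj_sorted <- pmin(cummax(adj_sorted), 1)
  adj <- numeric(m)
  adj[o] <- adj_sorted
  out <- data.frame(
    comparison = labels %||% sprintf("p%d", seq_len(m)),
    p_raw = p, p_adjusted = adj, stringsAsFactors = FALSE
  )
  class(out) <- c("posthoc_table", "data.frame")
  out
}

#' Pearson chi-square test of independence
#'
#' Plain Pearson chi-square without continuity correction, df = (r-1)(c-1).
#'
#' @param table Matrix of non-negative counts, at least 2 x 2, with no
#'   all-zero row or column.
#' @return A `test_result`.
#' @export
chi_square_test <- function(table) {
  m <- as.matrix(table)
  if (any(m < 0) || any(!is.finite(m))) {
    stop_navscrew("counts must be non-negative and finite", "navscrew_validation_error")
  }
  if (nrow(m) < 2L || ncol(m) < 2L) {
    stop_navscrew("contingency table must be at least 2 x 2",
                  "navscrew_degenerate_error")
  }
  rs <- rowSums(m); cs <- colSums(m)
  if (any(rs == 0) || any(cs == 0)) {
    stop_navscrew("contingency table has an all-zero row or column",
                  "navscrew_degenerate_error")
  }
  E <- outer(rs, cs) / sum(m)
  stat <- sum((m - E)^2 / E)
  df <- (nrow(m) - 1L) * (ncol(m) - 1L)
  test_result(stat, df, stats::pchisq(stat, df, lower.tail = FALSE),
              "Pearson chi-square")
}

#' Kruskal-Wallis rank-sum test
#'
#' Uses mid-ranks for ties and the standard tie correction; the p-value is
#' the chi-square approximation with k-1 degrees of freedom.
#'
#' @param groups List of at least 2 numeric samples, total N >= 3.
#' @return A `test_result`. When every observation is tied, H = 0 and p = 1.
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L) {
    stop_navscrew("kruskal_wallis needs at least 2 groups", "navscrew_degenerate_error")
  }
  k <- length(groups)
  v <- unlist(groups, use.names = FALSE)
  N <- length(v)
  if (N < 3L) {
    stop_navscrew("kruskal_wallis needs at least 3 observations in total",
                  "navscrew_degenerate_error")
  }
  g <- rep(seq_len(k), vapply(groups, length, integer(1)))
  rk <- rank(v)
  Rg <- tapply(rk, g, sum)
  n <- tabulate(g, k)
  H <- 12 / (N * (N + 1)) * sum(Rg^2 / n) - 3 * (N + 1)
  ties <- table(v)
  corr <- 1 - sum(ties^3 - ties) / (N^3 - N)
  if (corr <= 0) {
    H <- 0; p <- 1
  } else {
    H <- H / corr
    p <- stats::pchisq(H, k - 1L, lower.tail = FALSE)
  }
  test_result(H, k - 1L, p, "Kruskal-Wallis",
              group_summaries = summarize_groups(groups))
}

#' Compare screw deviations against the navigation registration error
#'
#' One-way ANOVA across the groups {head MADs, tip MADs, per-case
#' registration errors} followed by Holm-Sidak-adjusted pooled t post-tests
#' of each deviation group against the registration-error group. Deviation
#' metrics are per screw while the registration error is per case; this
#' mixing of analysis units is deliberate (it mirrors how navigated-accuracy
#' cohorts are conventionally reported) and can be avoided by aggregating
#' deviations per case first via `aggregate_per_case = TRUE`. Screw
#' direction is measured in degrees and is dimensionally incommensurable
#' with millimetre errors; it is only included on request
#' (`include_angle = TRUE`) and then flagged with a units-mismatch warning.
#'
#' @param devs Deviation table from [compare_screws()].
#' @param tre_by_case Named numeric vector: registration error (mm) per
#'   case id. Every case in `devs` must be present.
#' @param include_angle Include the angle group (see above).
#' @param aggregate_per_case Average deviations within case before testing.
#' @return List with `anova` (a `test_result`) and `posthoc`
#'   (a `posthoc_table`).
#' @export
deviations_vs_registration_error <- function(devs, tre_by_case,
                                             include_angle = FALSE,
                                             aggregate_per_case = FALSE) {
  cases <- unique(devs$case_id)
  missing_tre <- setdiff(cases, names(tre_by_case))
  if (length(missing_tre)) {
    stop_navscrew(sprintf("no registration error for case(s): %s",
                          paste(missing_tre, collapse = ", ")),
                  "navscrew_pairing_error")
  }
  pick <- function(col) {
    if (aggregate_per_case) {
      as.numeric(tapply(devs[[col]], devs$case_id, mean))
    } else {
      devs[[col]]
    }
  }
  groups <- list(head_mad = pick("mad_head_mm"), tip_mad = pick("mad_tip_mm"))
  if (include_angle) {
    warning("angle group included: degrees compared against millimetres (units mismatch)")
    groups$angle <- pick("angle_deg")
  }
  groups$registration_error <- as.numeric(tre_by_case[cases])
  av <- one_way_anova(groups)
  dev_groups <- setdiff(names(groups), "registration_error")
  praw <- vapply(dev_groups, function(g) {
    two_sample_t(groups[[g]], groups$registration_error)$p_value
  }, numeric(1))
  posthoc <- holm_sidak_adjust(
    praw, labels = paste(dev_groups, "vs registration_error")
  )
  list(anova = av, posthoc = posthoc)
}
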