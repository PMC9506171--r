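test_that("pooled t matches the hand-computed example", {
  r <- two_sample_t(c(1, 2, 3, 4), c(3, 4, 5, 6))
  expect_equal(r$statistic, -2.19089, tolerance = 1e-4)
  expect_equal(r$df, 6)
  expect_equal(r$p_value, 2 * pt(-2.190890, 6), tolerance = 1e-5)
  same <- two_sample_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  expect_error(two_sample_t(1, c(1, 2)), class = "navscrew_degenerate_error")
  expect_error(two_sample_t(c(1, 1, 1), c(1, 1)), class = "navscrew_degenerate_error")
})

test_that("one-way ANOVA matches the hand-computed example", {
  r <- one_way_anova(list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9)))
  expect_equal(r$statistic, 27)       # SSB 54 / 2 over SSW 6 / 6
  expect_equal(r$df, c(2, 6))
  ident <- one_way_anova(list(c(2, 2), c(2, 2)))
  expect_equal(ident$statistic, 0)
  expect_equal(ident$p_value, 1)
  expect_error(one_way_anova(list(c(1, 2))), class = "navscrew_degenerate_error")
})

test_that("ANOVA F on two groups equals the squared pooled t", {
  set.seed(31)
  for (i in 1:20) {
    x <- rnorm(sample(3:12, 1))
    y <- rnorm(sample(3:12, 1), 0.5)
    expect_equal(one_way_anova(list(x, y))$statistic,
                 two_sample_t(x, y)$statistic^2, tolerance = 1e-10)
  }
})

test_that("Holm-Sidak adjustment matches the step-down formula", {
  expect_equal(holm_sidak_adjust(0.05)$p_adjusted, 0.05)
  r <- holm_sidak_adjust(c(0.01, 0.04))
  expect_equal(r$p_adjusted, c(1 - 0.99^2, 0.04), tolerance = 1e-12)
  expect_equal(round(r$p_adjusted, 4), c(0.0199, 0.04))
  r3 <- holm_sidak_adjust(c(0.5, 0.5, 0.5))
  expect_true(all(r3$p_adjusted == r3$p_adjusted[1]))
  expect_true(all(r3$p_adjusted <= 1))
  expect_error(holm_sidak_adjust(c(0.5, 1.2)), class = "navscrew_validation_error")
})

test_that("Holm-Sidak is permutation-equivariant and never below raw p", {
  set.seed(32)
  for (i in 1:20) {
    p <- runif(sample(2:8, 1))
    adj <- holm_sidak_adjust(p)$p_adjusted
    expect_true(all(adj >= p - 1e-12))
    perm <- sample(length(p))
    expect_equal(holm_sidak_adjust(p[perm])$p_adjusted, adj[perm])
    # monotone in rank order
    o <- order(p)
    expect_true(all(diff(adj[o]) >= -1e-12))
  }
})

test_that("chi-square matches the 2x2 closed form", {
  r <- chi_square_test(matrix(c(20, 5, 5, 20), 2, 2))
  expect_equal(r$statistic, 18)  # n(ad-bc)^2 / product of margins
  expect_equal(r$df, 1)
  flat <- chi_square_test(matrix(10, 2, 2))
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p_value, 1)
  expect_error(chi_square_test(matrix(c(1, 2, 0, 0), 2, 2)),
               class = "navscrew_degenerate_error")
  expect_error(chi_square_test(matrix(1:3, 1, 3)),
               class = "navscrew_degenerate_error")
})

test_that("Kruskal-Wallis matches the hand-ranked example", {
  r <- kruskal_wallis(list(c(1, 2), c(3, 4), c(5, 6)))
  expect_equal(r$statistic, 12 / 42 * (9 / 2 + 49 / 2 + 121 / 2) - 21,
               tolerance = 1e-10)
  expect_equal(round(r$statistic, 4), 4.5714)
  ident <- kruskal_wallis(list(c(1, 1), c(1, 1)))
  expect_equal(ident$statistic, 0)
  expect_equal(ident$p_value, 1)
  expect_error(kruskal_wallis(list(1:3)), class = "navscrew_degenerate_error")
})

test_that("implementations agree with base R on random datasets", {
  set.seed(33)
  for (i in 1:150) {
    x <- rnorm(sample(4:15, 1), sd = runif(1, 0.5, 3))
    y <- rnorm(sample(4:15, 1), mean = runif(1, -1, 1))
    z <- rnorm(sample(4:15, 1))

    tp <- two_sample_t(x, y)
    ref <- t.test(x, y, var.equal = TRUE)
    expect_equal(tp$statistic, unname(ref$statistic), tolerance = 1e-8)
    expect_equal(tp$p_value, ref$p.value, tolerance = 1e-8)

    tw <- two_sample_t(x, y, variant = "welch")
    refw <- t.test(x, y)
    expect_equal(tw$statistic, unname(refw$statistic), tolerance = 1e-8)
    expect_equal(tw$df, unname(refw$parameter), tolerance = 1e-8)
    expect_equal(tw$p_value, refw$p.value, tolerance = 1e-8)

    av <- one_way_anova(list(x, y, z))
    g <- factor(rep(1:3, c(length(x), length(y), length(z))))
    refa <- summary(aov(c(x, y, z) ~ g))[[1]]
    expect_equal(av$statistic, refa[["F value"]][1], tolerance = 1e-8)
    expect_equal(av$p_value, refa[["Pr(>F)"]][1], tolerance = 1e-8)

    kw <- kruskal_wallis(list(x, y, z))
    refk <- kruskal.test(list(x, y, z))
    expect_equal(kw$statistic, unname(refk$statistic), tolerance = 1e-8)
    expect_equal(kw$p_value, refk$p.value, tolerance = 1e-8)

    m <- matrix(rpois(6, 15) + 1, 2, 3)
    cs <- chi_square_test(m)
    refc <- suppressWarnings(chisq.test(m, correct = FALSE))
    expect_equal(cs$statistic, unname(refc$statistic), tolerance = 1e-8)
    expect_equal(cs$p_value, refc$p.value, tolerance = 1e-8)
  }
})

test_that("Kruskal-Wallis tie correction matches base R under heavy ties", {
  set.seed(34)
  for (i in 1:30) {
    g <- lapply(1:3, function(k) sample(1:4, sample(5:10, 1), replace = TRUE))
    kw <- kruskal_wallis(g)
    refk <- kruskal.test(g)
    expect_equal(kw$statistic, unname(refk$statistic), tolerance = 1e-8)
    expect_equal(kw$p_value, refk$p.value, tolerance = 1e-8)
  }
})

test_that("deviation-vs-registration-error comparison behaves at both extremes", {
  devs <- data.frame(
    case_id = rep(sprintf("C%d", 1:10), each = 2),
    screw_id = rep(c("a", "b"), 10), level = "L4", side = "left",
    mad_head_mm = NA, mad_tip_mm = NA, angle_deg = 5,
    stringsAsFactors = FALSE
  )
  set.seed(35)
  base <- rnorm(20, 5, 0.3)
  tre <- setNames(rnorm(10, 5, 0.3), sprintf("C%d", 1:10))
  devs$mad_head_mm <- base
  devs$mad_tip_mm <- base + rnorm(20, 0, 0.3)
  same <- deviations_vs_registration_error(devs, tre)
  expect_true(all(same$posthoc$p_adjusted > 0.05))

  devs2 <- devs
  devs2$mad_head_mm <- devs$mad_head_mm + 5
  devs2$mad_tip_mm <- devs$mad_tip_mm + 5
  diff <- deviations_vs_registration_error(devs2, tre)
  expect_true(all(diff$posthoc$p_adjusted < 0.001))
  expect_lt(diff$anova$p_value, 0.001)

  expect_error(deviations_vs_registration_error(devs, tre[1:5]),
               class = "navscrew_pairing_error")
  expect_warning(deviations_vs_registration_error(devs, tre, include_angle = TRUE),
                 "units mismatch")
})
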