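make_pair <- function(dhead = c(0, 0, 0), rot_deg = 0, rot_axis = c(1, 0, 0),
                      length_mm = 45) {
  plan <- fixture_screw(head = c(0, 0, 0), tip = c(0, 0, length_mm),
                        role = "planned")
  R <- rotation_about_axis(rot_axis, rot_deg)
  tip_f <- as.numeric(R %*% c(0, 0, length_mm)) + dhead
  final <- fixture_screw(head = dhead, tip = tip_f, length_mm = length_mm,
                         role = "final")
  list(plan = plan, final = final)
}

test_that("identical screws give zero deviation everywhere", {
  p <- make_pair()
  d <- compare_screws(p$plan, p$final)
  expect_equal(d$mad_head_mm, 0)
  expect_equal(d$mad_tip_mm, 0)
  expect_equal(d$angle_deg, 0)
  expect_equal(d$dlength_mm, 0)
  expect_equal(d$ddiameter_mm, 0)
})

test_that("a pure translation moves head and tip equally with zero angle", {
  p <- make_pair(dhead = c(2, 0, 0))
  d <- compare_screws(p$plan, p$final)
  expect_equal(d$mad_head_mm, 2)
  expect_equal(d$mad_tip_mm, 2)
  expect_equal(d$angle_deg, 0, tolerance = 1e-9)
})

test_that("a rotation about the head gives the chord-length tip deviation", {
  # chord of a 5-degree rotation at radius 45: 2 * 45 * sin(2.5 deg)
  p <- make_pair(rot_deg = 5)
  d <- compare_screws(p$plan, p$final)
  expect_equal(d$mad_head_mm, 0)
  expect_equal(d$angle_deg, 5, tolerance = 1e-9)
  expect_equal(d$mad_tip_mm, 2 * 45 * sin(2.5 * pi / 180), tolerance = 1e-9)
  expect_equal(round(d$mad_tip_mm, 4), 3.9257)
})

test_that("deviations are invariant under a common rigid transform", {
  set.seed(12)
  for (i in 1:20) {
    p <- make_pair(dhead = rnorm(3), rot_deg = runif(1, 0, 10),
                   rot_axis = rnorm(3))
    d0 <- compare_screws(p$plan, p$final)
    tr <- random_rigid("navCT", "other")
    d1 <- compare_screws(transform_screws(tr, p$plan),
                         transform_screws(tr, p$final))
    expect_equal(d1$mad_head_mm, d0$mad_head_mm, tolerance = 1e-9)
    expect_equal(d1$mad_tip_mm, d0$mad_tip_mm, tolerance = 1e-9)
    expect_equal(d1$angle_deg, d0$angle_deg, tolerance = 1e-9)
  }
})

test_that("frame_map brings the plan into the final frame", {
  p <- make_pair(dhead = c(1, 1, 0))
  tr <- random_rigid("navCT", "controlCT")
  final_moved <- transform_screws(tr, p$final)
  expect_error(compare_screws(p$plan, final_moved), class = "navscrew_frame_error")
  d <- compare_screws(p$plan, final_moved, frame_map = tr)
  d0 <- compare_screws(p$plan, p$final)
  expect_equal(d$mad_head_mm, d0$mad_head_mm, tolerance = 1e-9)
  expect_equal(d$angle_deg, d0$angle_deg, tolerance = 1e-9)
})

test_that("swapping plan and final preserves MADs/angle and negates dims", {
  plan <- fixture_screw(head = c(0, 0, 0), tip = c(0, 0, 45), length_mm = 45,
                        role = "planned")
  final <- fixture_screw(head = c(1, 2, 0), tip = c(2, 1, 50.2),
                         length_mm = 50, diameter_mm = 7, role = "final")
  d <- compare_screws(plan, final)
  plan2 <- final; plan2$role <- "planned"
  final2 <- plan; final2$role <- "final"
  d2 <- compare_screws(plan2, final2)
  expect_equal(d2$mad_head_mm, d$mad_head_mm)
  expect_equal(d2$mad_tip_mm, d$mad_tip_mm)
  expect_equal(d2$angle_deg, d$angle_deg)
  expect_equal(d2$dlength_mm, -d$dlength_mm)
  expect_equal(d2$ddiameter_mm, -d$ddiameter_mm)
})

test_that("tip deviation obeys the head + chord + length-change bound", {
  set.seed(13)
  for (i in 1:30) {
    p <- make_pair(dhead = rnorm(3, 0, 3), rot_deg = runif(1, 0, 15),
                   rot_axis = rnorm(3))
    d <- compare_screws(p$plan, p$final)
    bound <- d$mad_head_mm +
      2 * p$plan$length_mm * sin(d$angle_deg * pi / 360) + abs(d$dlength_mm)
    expect_lte(d$mad_tip_mm, bound + 1e-9)
  }
})

test_that("pair_screws matches on case/screw id with deterministic order", {
  plans <- rbind(
    fixture_screw(screw_id = "L4_left", level = "L4", side = "left"),
    fixture_screw(screw_id = "L4_right", level = "L4", side = "right"),
    fixture_screw(case_id = "C2", screw_id = "L5_left", level = "L5"),
    fixture_screw(case_id = "C2", screw_id = "L3_left", level = "L3")
  )
  finals <- plans[c(3, 1, 4, 2), ]
  finals$role <- "final"
  pr <- pair_screws(plans, finals)
  expect_equal(pr$plan$screw_id, pr$final$screw_id)
  expect_equal(pr$plan$screw_id, c("L4_left", "L4_right", "L3_left", "L5_left"))
  expect_equal(nrow(pr$plan), 4L)
})

test_that("pair_screws names unmatched and duplicated screws", {
  plans <- fixture_screw(screw_id = "lonely")
  finals <- fixture_screw(screw_id = "other", role = "final")
  err <- tryCatch(pair_screws(plans, finals), error = identity)
  expect_s3_class(err, "navscrew_pairing_error")
  expect_match(conditionMessage(err), "lonely")
  dup <- rbind(plans, plans)
  expect_error(pair_screws(dup, finals), class = "navscrew_pairing_error")
})

test_that("per-level summaries use sample SD and flag sparse levels", {
  devs <- data.frame(
    case_id = "C1", screw_id = sprintf("s%d", 1:6),
    level = c("L4", "L4", "L4", "L4", "L1", "L1"),
    side = "left",
    mad_head_mm = c(4, 6, 5, 5, 1, 2), mad_tip_mm = 1, angle_deg = 1,
    stringsAsFactors = FALSE
  )
  out <- summarize_by_level(devs, min_n = 3)
  l4 <- out$by_level[out$by_level$level == "L4" &
                       out$by_level$metric == "mad_head_mm", ]
  expect_equal(l4$mean, 5)
  expect_equal(l4$sd, sd(c(4, 6, 5, 5)))
  expect_false(l4$excluded_from_stats)
  expect_identical(out$excluded_levels, "L1")
  l1 <- out$by_level[out$by_level$level == "L1" &
                       out$by_level$metric == "mad_head_mm", ]
  expect_equal(l1$n, 2L)          # summarized even though excluded from stats
  expect_equal(round(out$by_level$sd[out$by_level$level == "L4" &
                                       out$by_level$metric == "mad_head_mm"] /
                       sqrt(1), 4), 0.8165)
  expect_false("L2" %in% out$by_level$level)  # absent levels absent
})

test_that("simple two-value summary matches hand computation", {
  devs <- data.frame(case_id = "C1", screw_id = c("a", "b"), level = "L4",
                     side = "left", mad_head_mm = c(4, 6), mad_tip_mm = c(4, 6),
                     angle_deg = c(4, 6), stringsAsFactors = FALSE)
  s <- summarize_by_level(devs, min_n = 2)$by_level
  expect_true(all(s$mean == 5))
  expect_equal(unique(round(s$sd, 4)), 1.4142)
})

test_that("dimension comparison reports signed and absolute means", {
  base <- data.frame(length_planned_mm = 45, length_final_mm = 45,
                     diameter_planned_mm = 6.5, diameter_final_mm = 6.5)
  devs0 <- cbind(base, dlength_mm = 0, ddiameter_mm = 0)
  expect_equal(compare_dimensions(devs0)$mean_diff, c(0, 0))
  devs1 <- data.frame(
    length_planned_mm = c(45, 45), length_final_mm = c(50, 40),
    diameter_planned_mm = 6.5, diameter_final_mm = 6.5,
    dlength_mm = c(5, -5), ddiameter_mm = 0
  )
  cd <- compare_dimensions(devs1)
  expect_equal(cd$mean_diff[cd$dimension == "length_mm"], 0)
  expect_equal(cd$mean_abs_diff[cd$dimension == "length_mm"], 5)
  devs2 <- data.frame(
    length_planned_mm = rep(45, 3), length_final_mm = rep(50, 3),
    diameter_planned_mm = 6.5, diameter_final_mm = 6.5,
    dlength_mm = rep(5, 3), ddiameter_mm = 0
  )
  expect_equal(compare_dimensions(devs2)$mean_diff[1], 5)
})

test_that("mean head deviation under isotropic noise follows the chi(3) mean", {
  set.seed(99)
  sigma <- 2
  n <- 30000
  noise <- matrix(rnorm(3 * n, 0, sigma), n, 3)
  mad <- sqrt(rowSums(noise^2))
  expect_equal(mean(mad), 2 * sqrt(2 / pi) * sigma, tolerance = 0.02)
})
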