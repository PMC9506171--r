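test_that("a zero-noise cohort has zero deviations, grade A, zero TRE", {
  cfg <- simulation_config(
    n_cases = 4, seed = 2, sigma_fle_mm = 0, sigma_coreg_mm = 0,
    sigma_head_mm = 0, sigma_angle_deg = 0, sigma_frame_rot_deg = 0,
    sigma_frame_trans_mm = 0
  )
  co <- simulate_cohort(cfg)
  expect_true(all(co$ground_truth$cases$true_tre_mm < 1e-9))
  rep <- run_pipeline(pipeline_config(cohort = co))
  expect_equal(rep$cohort$n_cases_excluded, 0L)
  expect_lt(max(rep$deviations$mad_head_mm), 1e-9)
  expect_lt(max(rep$deviations$mad_tip_mm), 1e-9)
  # arccos is ill-conditioned at 0; 1e-5 degrees is numerical zero here
  expect_lt(max(rep$deviations$angle_deg), 1e-5)
  expect_true(all(rep$deviations$grade == "A"))
  expect_true(all(rep$tre_by_case < 1e-9))
})

test_that("the same seed reproduces the cohort exactly", {
  cfg <- simulation_config(n_cases = 6, seed = 123)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$screws, b$screws)
  expect_identical(a$landmarks, b$landmarks)
  expect_identical(a$covariates, b$covariates)
  c_ <- simulate_cohort(simulation_config(n_cases = 6, seed = 124))
  expect_false(identical(a$screws, c_$screws))
})

test_that("config validation rejects bad mixes and negative noise", {
  expect_error(simulation_config(sigma_head_mm = -1), class = "navscrew_config_error")
  expect_error(simulation_config(level_mix = c(L1 = 0.5, L2 = 0.2, L3 = 0.1,
                                               L4 = 0.1, L5 = 0.05, S1 = 0.01)),
               class = "navscrew_config_error")
  expect_error(simulation_config(n_cases = 2, n_shift_cases = 3),
               class = "navscrew_config_error")
  cfg <- simulation_config(sigma_angle_deg = 5)   # scalar broadcast
  expect_equal(unname(cfg$sigma_angle_deg), rep(5, 6))
})

test_that("injected head noise is recovered via the chi(3) mean relation", {
  cfg <- simulation_config(n_cases = 700, seed = 17, sigma_head_mm = 3,
                           sigma_angle_deg = 6)
  co <- simulate_cohort(cfg)
  gt <- co$ground_truth$screws
  expect_gt(nrow(gt), 3000)
  sigma_head_hat <- mean(gt$true_head_mad_mm) / (2 * sqrt(2 / pi))
  expect_equal(sigma_head_hat, 3, tolerance = 0.05)
  sigma_angle_hat <- mean(gt$true_tilt_deg) / sqrt(2 / pi)
  expect_equal(sigma_angle_hat, 6, tolerance = 0.05)
})

test_that("export/import round-trips the cohort losslessly", {
  co <- simulate_cohort(simulation_config(n_cases = 3, seed = 9,
                                          per_level_shift_mm = 5, n_shift_cases = 1))
  dir <- withr::local_tempdir()
  export_cohort(co, dir)
  expect_true(all(file.exists(file.path(dir, c(
    "screws.csv", "corridors.csv", "landmarks.csv", "covariates.csv",
    "ground_truth.json", "config.json"
  )))))
  co2 <- import_cohort(dir)
  num <- c("head_x", "head_y", "head_z", "tip_x", "tip_y", "tip_z")
  expect_equal(as.matrix(co2$screws[, num]), as.matrix(co$screws[, num]),
               tolerance = 1e-9)
  expect_identical(co2$screws$screw_id, co$screws$screw_id)
  expect_equal(co2$landmarks$src_x, co$landmarks$src_x, tolerance = 1e-9)
  # ground truth carries the true frame transform
  t1 <- co$ground_truth$transforms[[1]]
  t2 <- co2$ground_truth$transforms[[1]]
  expect_equal(t2$rotation, t1$rotation, tolerance = 1e-9)
  expect_equal(t2$translation, t1$translation, tolerance = 1e-9)
  expect_equal(co2$config$sigma_head_mm, co$config$sigma_head_mm)
})

test_that("an empty-ish cohort still exports valid headers", {
  co <- simulate_cohort(simulation_config(n_cases = 1, seed = 1))
  co$screws <- co$screws[0, ]
  co$corridors <- co$corridors[0, ]
  dir <- withr::local_tempdir()
  export_cohort(co, dir)
  re <- utils::read.csv(file.path(dir, "screws.csv"))
  expect_equal(nrow(re), 0L)
  expect_true(all(c("case_id", "head_x", "frame") %in% names(re)))
})

test_that("shifted cases and only shifted cases are excluded", {
  cfg <- simulation_config(n_cases = 20, seed = 41, per_level_shift_mm = 5,
                           n_shift_cases = 3)
  co <- simulate_cohort(cfg)
  rep <- suppressMessages(run_pipeline(pipeline_config(cohort = co, grade = FALSE)))
  truth <- sort(co$ground_truth$cases$case_id[co$ground_truth$cases$shifted])
  expect_identical(sort(rep$exclusions$case_id), truth)
  # without shifts, nothing is excluded
  co0 <- simulate_cohort(simulation_config(n_cases = 20, seed = 41))
  rep0 <- run_pipeline(pipeline_config(cohort = co0, grade = FALSE))
  expect_equal(nrow(rep0$exclusions), 0L)
})

test_that("covariate draws follow the configured diagnosis mix", {
  cfg <- simulation_config(n_cases = 600, seed = 55)
  co <- simulate_cohort(cfg)
  counts <- table(factor(co$covariates$diagnosis, levels = names(cfg$diagnosis_mix)))
  gof <- chi_square_gof <- suppressWarnings(
    chisq.test(as.integer(counts), p = as.numeric(cfg$diagnosis_mix))
  )
  expect_gt(gof$p.value, 0.001)
  expect_true(abs(mean(co$covariates$age) - cfg$age_mean) < 2)
})

test_that("grade severity is stochastically monotone in head noise", {
  br <- function(sig, seed) {
    co <- simulate_cohort(simulation_config(n_cases = 40, seed = seed,
                                            sigma_head_mm = sig,
                                            sigma_angle_deg = 5))
    finals <- co$screws[co$screws$role == "final", ]
    # grade in the planning frame using ground-truth transforms (fast, exact)
    g <- lapply(unique(finals$case_id), function(cid) {
      tinv <- invert_transform(co$ground_truth$transforms[[cid]])
      grade_screws(transform_screws(tinv, finals[finals$case_id == cid, ]),
                   co$corridors[co$corridors$case_id == cid, ])
    })
    do.call(rbind, g)$breach_mm
  }
  for (seed in c(7, 19)) {
    b_small <- br(1, seed)
    b_large <- br(4, seed)
    q <- c(0.25, 0.5, 0.75, 0.9)
    expect_true(all(quantile(b_large, q) >= quantile(b_small, q)))
  }
})

test_that("simulated level frequencies approximate the configured mix", {
  co <- simulate_cohort(simulation_config(n_cases = 1500, seed = 70))
  planned <- co$screws[co$screws$role == "planned", ]
  freq <- prop.table(table(factor(planned$level, levels = names(LEVEL_MIX <- c(
    L1 = 2, L2 = 8, L3 = 24, L4 = 40, L5 = 44, S1 = 22) / 140))))
  expect_lt(max(abs(as.numeric(freq) - as.numeric(LEVEL_MIX))), 0.03)
})
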