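test_that("jitter-free phantoms invert exactly through the whole pipeline", {
  expect_equal(measure_abza(generate_landmarks(phantom_spec(45)))$abza_deg, 45,
               tolerance = 1e-6)
  zero <- generate_landmarks(phantom_spec(0))
  expect_equal(measure_abza(zero)$abza_deg, 0, tolerance = 1e-9)

  sch <- grading_scheme()
  iv <- grade_intervals(sch)
  for (g in 0:4) {
    th <- (iv$lower_deg[g + 1] + iv$upper_deg[g + 1]) / 2
    m <- measure_abza(generate_landmarks(
      phantom_spec(th, rotation_deg = 17 * g, translation = c(g, -g),
                   n_candidates = 3L, fan_deg = 4)))
    expect_identical(abza_grade(abza_trans(m$abza_deg, sch), sch), as.integer(g))
    expect_lt(abs(m$abza_deg - th), 1e-6)
  }
})

test_that("round-trip recovery holds on a fine angle grid under random rigid motion", {
  set.seed(3)
  grid <- c(0.1, seq(1, 90, length.out = 45))
  for (th in grid) {
    sp <- phantom_spec(th, rotation_deg = runif(1, 0, 360),
                       translation = runif(2, -100, 100),
                       radius = runif(1, 2, 40))
    expect_lt(abs(measure_abza(generate_landmarks(sp))$abza_deg - th), 1e-6)
  }
})

test_that("symmetric landmark jitter leaves the measured angle unbiased", {
  set.seed(101)
  meas <- vapply(1:1000, function(i)
    measure_abza(generate_landmarks(phantom_spec(57.5, jitter_sd = 0.5)))$abza_deg,
    0)
  mc_se <- sd(meas) / sqrt(length(meas))
  expect_lt(abs(mean(meas) - 57.5), 3 * mc_se)
})

test_that("intercept calibration matches closed forms and its target", {
  flat <- cohort_sim_config(beta_age = 0, beta_goodcollat = 0, beta_mtici = 0,
                            target_prevalence = 0.343)
  expect_equal(calibrate_intercept(flat), qlogis(0.343), tolerance = 1e-9)
  flat5 <- cohort_sim_config(beta_age = 0, beta_goodcollat = 0, beta_mtici = 0,
                             target_prevalence = 0.5)
  expect_equal(calibrate_intercept(flat5), 0, tolerance = 1e-9)

  cfg <- cohort_sim_config(n = 1e5)
  cfg$beta0 <- calibrate_intercept(cfg)
  coh <- generate_cohort(cfg, seed = 12)
  expect_lt(abs(mean(coh$mrs_90 <= 2) - 0.343), 0.01)
})

test_that("identical seeds give bitwise-identical cohorts", {
  cfg <- cohort_sim_config(n = 300, beta0 = 2.4)
  expect_identical(generate_cohort(cfg, seed = 7), generate_cohort(cfg, seed = 7))
  expect_false(identical(generate_cohort(cfg, seed = 7),
                         generate_cohort(cfg, seed = 8)))
})

test_that("grade-by-TOAST and grade marginals match their configured targets", {
  cfg <- cohort_sim_config(n = 1e5, beta0 = 2.4)
  coh <- generate_cohort(cfg, seed = 5)
  good <- coh$abza_grade > 2
  expect_lt(abs(mean(good[coh$toast == "LAA"]) - 23 / 44), 0.01)
  expect_lt(abs(mean(good[coh$toast == "CE"]) - 10 / 59), 0.01)
  # marginal grade distribution vs its configured probabilities (3 MC-SE)
  p_good <- sum(cfg$toast_p * cfg$p_good_by_toast)
  p_marg <- c((1 - p_good) * cfg$grade_within_poor,
              p_good * cfg$grade_within_good)
  emp <- tabulate(coh$abza_grade + 1L, 5L) / nrow(coh)
  mc_se <- sqrt(p_marg * (1 - p_marg) / nrow(coh))
  expect_true(all(abs(emp - p_marg) < 3.5 * mc_se))
  # angles always grade back to the generated grade
  expect_identical(abza_grade(abza_trans(coh$abza_deg[1:2000])), coh$abza_grade[1:2000])
})

test_that("invalid configurations are rejected", {
  expect_error(cohort_sim_config(toast_p = c(LAA = 0.5, CE = 0.6, other = 0.1)),
               "sum to 1")
  expect_error(cohort_sim_config(p_good_by_toast = c(LAA = 1.2, CE = 0.1,
                                                     other = 0.5)),
               "\\[0, 1\\]")
  expect_error(calibrate_intercept(
    cohort_sim_config(beta_goodcollat = 1e8, target_prevalence = 0.001)),
    "unreachable")
})
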