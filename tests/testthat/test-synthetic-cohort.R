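test_that("constructors validate their invariants", {
  expect_error(trajectory_truth("x", 1:5), "degree")
  expect_error(trajectory_truth("x", 1, deviation_rate = -1), ">= 0")
  expect_error(trajectory_truth("x", 1, noise_sd = 0), "> 0")
  expect_error(trajectory_truth("x", 1, lr_split = 1.2), "strictly between")
  expect_error(cohort_spec("c", "control", 0, c(1, 10)), ">= 1")
  expect_error(cohort_spec("c", "control", 5, c(10, 10)), "min < max")
  expect_error(cohort_spec("c", "patient", 5, c(1, 10)))
  expect_error(simulate_cohort(list(), list(trajectory_truth("x", 1)), 1),
               "non-empty")
  tt <- trajectory_truth("x", 1)
  expect_error(simulate_cohort(list(cohort_spec("c", "control", 2, c(1, 9))),
                               list(tt, tt), 1), "unique")
})

test_that("generated z-scores equal the hinge trajectory when noise is negligible", {
  truths <- list(
    trajectory_truth("thal", c(0.5, 0.01, -2e-4), noise_sd = 1e-9,
                     onset_age = 55, deviation_rate = 0.1,
                     ref_mean = 1.0, ref_sd = 0.1),
    trajectory_truth("stem", c(0.9, -0.018), noise_sd = 1e-9,
                     lr_split = NA, ref_mean = 1.6, ref_sd = 0.12))
  specs <- list(cohort_spec("HC", "control", 40, c(1, 100)),
                cohort_spec("PSP", "case", 40, c(55, 86)))
  sim <- simulate_cohort(specs, truths, seed = 5)
  s <- sim$subjects
  z_obs <- (100 * (s$thal_L + s$thal_R) / s$tiv_mm3 - 1.0) / 0.1
  hinge <- 0.5 + 0.01 * s$age - 2e-4 * s$age^2 -
    ifelse(s$group == "case", 0.1 * pmax(0, s$age - 55), 0)
  expect_equal(z_obs, hinge, tolerance = 1e-6)
  # a case 10 years past onset sits 1.0 z below the healthy curve
  cases <- s$group == "case"
  healthy_at_age <- 0.5 + 0.01 * s$age - 2e-4 * s$age^2
  expect_equal(z_obs[cases] - healthy_at_age[cases],
               -0.1 * pmax(0, s$age[cases] - 55), tolerance = 1e-6)
  # midline structure: single column, linear trajectory
  z_stem <- (100 * s$stem / s$tiv_mm3 - 1.6) / 0.12
  expect_equal(z_stem[!cases], 0.9 - 0.018 * s$age[!cases], tolerance = 1e-6)
})

test_that("zero deviation makes cases and controls share one law", {
  tr <- list(trajectory_truth("a", c(0.2, -0.002), noise_sd = 1e-9,
                              deviation_rate = 0, ref_mean = 1, ref_sd = 0.1))
  specs <- list(cohort_spec("HC", "control", 30, c(55, 86)),
                cohort_spec("PSP", "case", 30, c(55, 86)))
  s <- simulate_cohort(specs, tr, seed = 2)$subjects
  z <- (100 * (s$a_L + s$a_R) / s$tiv_mm3 - 1) / 0.1
  expect_equal(z, 0.2 - 0.002 * s$age, tolerance = 1e-6)
})

test_that("simulation is deterministic in the seed", {
  sc <- recovery_scenario(n_controls = 60, n_cases = 15)
  s1 <- simulate_cohort(sc$specs, sc$truths, seed = 9)
  s2 <- simulate_cohort(sc$specs, sc$truths, seed = 9)
  s3 <- simulate_cohort(sc$specs, sc$truths, seed = 10)
  expect_identical(s1$subjects, s2$subjects)
  expect_identical(s1$truth, s2$truth)
  expect_false(isTRUE(all.equal(s1$subjects$structure_01_L,
                                s3$subjects$structure_01_L)))
  # truth table does not depend on the seed
  expect_identical(s1$truth, s3$truth)
})

test_that("left and right volumes sum to the intended total for any split", {
  for (split in c(0.3, 0.5, 0.62)) {
    tr <- list(trajectory_truth("a", 0.1, lr_split = split,
                                ref_mean = 1, ref_sd = 0.1))
    sp <- list(cohort_spec("HC", "control", 25, c(1, 100)))
    s <- simulate_cohort(sp, tr, seed = 3)$subjects
    total <- s$a_L + s$a_R
    expect_equal(s$a_L / total, rep(split, 25), tolerance = 1e-12)
    # total consistent with the z-model: invert and check finite z
    z <- (100 * total / s$tiv_mm3 - 1) / 0.1
    expect_true(all(is.finite(z)))
  }
})

test_that("empirical age-bin means converge to the healthy polynomial", {
  cf <- c(-0.5, 0.06, -7e-4)
  tr <- list(trajectory_truth("a", cf, noise_sd = 0.5, ref_mean = 1,
                              ref_sd = 0.1))
  sp <- list(cohort_spec("HC", "control", 6000, c(1, 100)))
  s <- simulate_cohort(sp, tr, seed = 4)$subjects
  z <- (100 * (s$a_L + s$a_R) / s$tiv_mm3 - 1) / 0.1
  for (centre in c(20, 50, 80)) {
    inbin <- abs(s$age - centre) < 2.5
    se <- 0.5 / sqrt(sum(inbin))
    mid_true <- mean(cf[1] + cf[2] * s$age[inbin] + cf[3] * s$age[inbin]^2)
    expect_lt(abs(mean(z[inbin]) - mid_true), 3 * se)
  }
})

test_that("negative implied volumes are clamped with a warning count", {
  # reference stats chosen so low z values imply negative raw volume
  tr <- list(trajectory_truth("tiny", c(-5), noise_sd = 2,
                              ref_mean = 0.001, ref_sd = 0.01))
  sp <- list(cohort_spec("HC", "control", 200, c(1, 100)))
  expect_warning(sim <- simulate_cohort(sp, tr, seed = 6), "clamped")
  expect_gt(sim$n_clamped, 0)
  expect_true(all(sim$subjects$tiny_L + sim$subjects$tiny_R > 0))
})

test_that("truth table echoes every ground-truth field", {
  tr <- trajectory_truth("x", c(1, 2), noise_sd = 0.7, onset_age = 60,
                         deviation_rate = 0.05, lr_split = 0.45,
                         ref_mean = 2, ref_sd = 0.2)
  tab <- truth_table(list(tr))
  expect_equal(tab$c0, 1)
  expect_equal(tab$c1, 2)
  expect_equal(tab$c2, 0)
  expect_equal(tab$onset_age, 60)
  expect_equal(tab$deviation_rate, 0.05)
  expect_equal(tab$noise_sd, 0.7)
  expect_equal(tab$lr_split, 0.45)
  expect_equal(tab$ref_sd, 0.2)
})
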