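test_that("left/right summation adds symmetric pairs and passes midline through", {
  df <- data.frame(thalamus_L = 7000, thalamus_R = 7200, brainstem = 22000)
  out <- combine_lr(df)
  expect_equal(out$thalamus, 14200)
  expect_equal(out$brainstem, 22000)
  expect_false("thalamus_L" %in% names(out))
  expect_error(combine_lr(data.frame(thalamus_L = 7000, brainstem = 1)),
               "thalamus.*right hemisphere")
})

test_that("TIV normalization is a percentage, scale-invariant, and guarded", {
  expect_equal(normalize_to_tiv(15000, 1.5e6), 1.0)
  expect_equal(normalize_to_tiv(0, 1.5e6), 0.0)
  expect_equal(normalize_to_tiv(123 * 7, 4.5e5 * 7),
               normalize_to_tiv(123, 4.5e5))
  expect_error(normalize_to_tiv(1, 0), "positive")
  expect_error(normalize_to_tiv(1, -5), "positive")
})

test_that("z-scoring standardizes against the reference and stores its stats", {
  set.seed(1)
  ref <- rnorm(50, 10, 2)
  zs <- zscore(ref)
  expect_equal(mean(zs$z), 0, tolerance = 1e-12)
  expect_equal(sd(zs$z), 1, tolerance = 1e-12)
  expect_equal(zscore(mean(ref), ref)$z, 0)
  expect_equal(zscore(mean(ref) + 2 * sd(ref), ref)$z, 2)
  expect_error(zscore(1:3, c(5, 5, 5)), "variance")
  expect_error(zscore(1, 7), "at least 2")
})

test_that("KS normality flags non-normal samples and degenerate input", {
  set.seed(42)
  normal <- rnorm(5000)
  ks_n <- ks_normality(normal)
  expect_identical(ks_n$status, "tested")
  expect_false(ks_n$reject)
  # statistic agrees with a direct empirical-CDF computation
  z <- sort((normal - mean(normal)) / sd(normal))
  n <- length(z)
  d_manual <- max(pmax(abs(seq_len(n) / n - pnorm(z)),
                       abs((seq_len(n) - 1) / n - pnorm(z))))
  expect_equal(ks_n$statistic, d_manual, tolerance = 1e-12)

  expo <- rexp(5000)
  expect_true(ks_normality(expo)$reject)

  expect_identical(ks_normality(rep(3, 20))$status, "untested")
  expect_identical(ks_normality(rnorm(5))$status, "untested")
})

test_that("disease training set keeps cases plus strictly younger controls", {
  ctl <- data.frame(age = c(50, 60), group = "control")
  cas <- data.frame(age = c(55, 70), group = "case")
  out <- build_disease_training_set(ctl, cas)
  expect_equal(nrow(out), 3)
  expect_equal(sort(out$age), c(50, 55, 70))

  # the printed cohort arithmetic: 5743 controls younger than the
  # youngest of 62 patients, combined set of 5805
  set.seed(7)
  young <- data.frame(age = runif(5743, 1, 54.9), group = "control")
  old <- data.frame(age = runif(2427, 55, 100), group = "control")
  cases <- data.frame(age = c(55, runif(61, 55.1, 86)), group = "case")
  out2 <- build_disease_training_set(rbind(young, old), cases)
  expect_equal(nrow(out2), 5805)

  # all controls older than every case -> cases only
  out3 <- build_disease_training_set(data.frame(age = 90:95, group = "control"),
                                     cases)
  expect_equal(nrow(out3), 62)
  expect_error(build_disease_training_set(ctl, ctl[0, ]), "at least one case")
})

test_that("no retained control is at or above the youngest case age", {
  set.seed(11)
  for (i in 1:20) {
    ctl <- data.frame(age = runif(80, 1, 100), group = "control")
    cas <- data.frame(age = runif(10, 40, 90), group = "case")
    out <- build_disease_training_set(ctl, cas)
    expect_true(all(out$age[out$group == "control"] < min(cas$age)))
    expect_equal(nrow(out), 10 + sum(ctl$age < min(cas$age)))
  }
})

test_that("subject tables round-trip through CSV at full precision", {
  sc <- recovery_scenario(n_controls = 25, n_cases = 10)
  sim <- simulate_cohort(sc$specs, sc$truths[1:2], seed = 8)
  path <- withr::local_tempfile(fileext = ".csv")
  write_subject_table(sim$subjects, path)
  back <- read_subject_table(path)
  expect_identical(back$age, sim$subjects$age)
  expect_identical(back$tiv_mm3, sim$subjects$tiv_mm3)
  expect_identical(back$structure_01_L, sim$subjects$structure_01_L)
  expect_identical(back$subject_id, sim$subjects$subject_id)
})

test_that("table validation names the offence", {
  good <- data.frame(subject_id = "s1", cohort_id = "c", group = "control",
                     sex = "F", age = 30, tiv_mm3 = 1.4e6, thal = 15000)
  expect_silent(validate_subject_table(good))
  expect_error(validate_subject_table(good[, -5]), "age")
  bad_age <- good; bad_age$age <- NA
  expect_error(validate_subject_table(bad_age), "age")
  bad_group <- good; bad_group$group <- "patient"
  expect_error(validate_subject_table(bad_group), "group")
  bad_tiv <- good; bad_tiv$tiv_mm3 <- -1
  expect_error(validate_subject_table(bad_tiv), "tiv")
  with_na <- rbind(good, good); with_na$thal[2] <- NA
  expect_warning(validate_subject_table(with_na), "missing structure")
})

test_that("structure metadata declares symmetry and anatomical groups", {
  meta <- default_structure_metadata()
  expect_true("thalamus" %in% meta$symmetric)
  expect_true("brainstem" %in% meta$midline)
  expect_identical(unname(meta$grouping_map["putamen"]), "striatum")
  expect_identical(unname(meta$grouping_map["frontal_pole"]), "frontal_cortex")
  # YAML route reads the same content
  yml <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(symmetric = "a", midline = "b",
                        groups = list(g = c("a", "b"))), yml)
  m2 <- read_structure_metadata(yml)
  expect_identical(unname(m2$grouping_map["a"]), "g")
})

test_that("model-outlier flags follow the 2-residual-SD rule", {
  set.seed(3)
  age <- runif(200, 1, 100)
  z <- 0.5 - 0.01 * age + rnorm(200, 0, 0.4)
  m <- fit_trajectory(age, z)
  probe_ages <- c(30, 50, 70)
  mu <- predict(m, probe_ages)
  probe_vals <- mu + c(2.5, -1.9, 0) * m$residual_sd
  expect_identical(flag_model_outliers(probe_ages, probe_vals, m),
                   c(TRUE, FALSE, FALSE))
  # points exactly on the curve are never flagged
  expect_false(any(flag_model_outliers(probe_ages, mu, m)))
})
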