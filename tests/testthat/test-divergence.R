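# shared small fits for identity/constant cases
make_flat_model <- function(level, n = 400, sd = 0.01, seed = 1,
                            structure = "s") {
  set.seed(seed)
  age <- runif(n, 1, 100)
  fit_trajectory(age, level + rnorm(n, 0, sd), structure = structure,
                 group = "control")
}

test_that("identical models yield a zero distance curve and no divergence", {
  set.seed(31)
  age <- runif(300, 1, 100)
  z <- 0.5 - 0.01 * age + rnorm(300, 0, 0.5)
  m <- fit_trajectory(age, z, structure = "s")
  g <- seq(5, 95, 0.5)
  dc <- distance_curve(m, m, g)
  expect_true(all(dc$distance == 0))
  dd <- detect_divergence(m, m, g)
  expect_false(dd$diverged)
  expect_identical(dd$direction, "none")
  expect_true(is.na(dd$onset_age))
  expect_equal(dd$distance_at_ref, 0)
})

test_that("well-separated flat models diverge from the first grid age", {
  m0 <- make_flat_model(0, seed = 32)
  m1 <- make_flat_model(-1, seed = 33)
  g <- seq(5, 90, 0.5)
  dc <- distance_curve(m0, m1, g)
  expect_equal(dc$distance, rep(1, length(g)), tolerance = 0.01)
  dd <- detect_divergence(m0, m1, g)
  expect_true(dd$diverged)
  expect_identical(dd$direction, "case_smaller")
  expect_equal(dd$onset_age, g[1])
  # and the reversed pair is an anomaly, not atrophy
  rev <- detect_divergence(m1, m0, g)
  expect_identical(rev$direction, "case_larger")
})

test_that("structure mismatch and malformed grids are rejected", {
  m1 <- make_flat_model(0, structure = "thalamus")
  m2 <- make_flat_model(0, structure = "pallidum")
  expect_error(distance_curve(m1, m2, 50:60), "different structures")
  m3 <- make_flat_model(0, structure = "thalamus", seed = 5)
  expect_error(detect_divergence(m1, m3, c(60, 50)), "increasing")
})

test_that("distance at the reference age is the difference of model means", {
  m_h <- make_flat_model(0.5, seed = 34)
  m_d <- make_flat_model(-1.5, seed = 35)
  expect_equal(distance_at_reference(m_h, m_d, 90), 2.0, tolerance = 0.01)
  expect_error(distance_at_reference(m_h, m_d, 140), "outside")
})

test_that("hinge truth is recovered up to the polynomial approximation floor", {
  # large n, small noise: what remains is the bias of approximating a
  # hinge with a cubic, which an independent noiseless least-squares
  # refit quantifies
  set.seed(36)
  h <- function(a) 0.2 + 0.01 * a - 2e-4 * a^2
  age_c <- runif(20000, 1, 100)
  age_p <- runif(2000, 55, 86)
  z_c <- h(age_c) + rnorm(20000, 0, 0.1)
  z_p <- h(age_p) - 0.1 * pmax(0, age_p - 60) + rnorm(2000, 0, 0.1)
  hm <- fit_trajectory(age_c, z_c, structure = "s", group = "control")
  keep <- age_c < min(age_p)
  ad <- c(age_c[keep], age_p)
  zd <- c(z_c[keep], z_p)
  dm <- fit_trajectory(ad, zd, structure = "s", group = "case")
  g <- seq(2, 86, 0.5)
  est <- distance_curve(hm, dm, g)$distance

  # independent noiseless oracle: least-squares cubic of the exact hinge
  # trajectory on the same design
  od <- lm(y ~ poly(a, 3, raw = TRUE),
           data = data.frame(a = ad, y = h(ad) - ifelse(ad %in% age_p,
             0.1 * pmax(0, ad - 60), 0)))
  oh <- lm(y ~ poly(a, 2, raw = TRUE),
           data = data.frame(a = age_c, y = h(age_c)))
  oracle_dist <- predict(oh, data.frame(a = g)) - predict(od, data.frame(a = g))
  expect_lt(max(abs(est - oracle_dist)), 0.05)

  # the approximation floor itself: within ~0.35 z of the true hinge
  true_d <- 0.1 * pmax(0, g - 60)
  expect_lt(max(abs(est - true_d)), 0.35)

  # severity at 90 carries the same smoothing bias; the estimate agrees
  # with the oracle refit far more tightly than with the raw hinge value
  d90 <- distance_at_reference(hm, dm, 90)
  oracle_d90 <- unname(predict(oh, data.frame(a = 90)) -
                         predict(od, data.frame(a = 90)))
  expect_lt(abs(d90 - oracle_d90), 0.05)
  expect_lt(abs(d90 - 3.0), 0.6)
})

test_that("detected onset matches a brute-force recomputation of the criterion", {
  set.seed(37)
  h <- function(a) -0.5 + 0.06 * a - 7e-4 * a^2
  age_c <- runif(2000, 1, 100)
  age_p <- runif(60, 55, 86)
  z_c <- h(age_c) + rnorm(2000, 0, 0.8)
  z_p <- h(age_p) - 0.08 * pmax(0, age_p - 62) + rnorm(60, 0, 0.8)
  hm <- fit_trajectory(age_c, z_c, structure = "s", group = "control")
  keep <- age_c < min(age_p)
  ad <- c(age_c[keep], age_p)
  zd <- c(z_c[keep], z_p)
  dm <- fit_trajectory(ad, zd, structure = "s", group = "case")
  g <- seq(2, 86, 0.5)
  est <- detect_divergence(hm, dm, g)
  oracle <- oracle_divergence_onset(age_c, z_c, ad, zd, g)
  expect_true(est$diverged)
  expect_false(is.na(oracle))
  expect_lt(abs(est$onset_age - oracle), 5)
})

test_that("band non-overlap always implies Welch rejection at the same level", {
  set.seed(38)
  violations <- 0
  for (i in 1:100) {
    n1 <- sample(30:200, 1); n2 <- sample(30:200, 1)
    d <- sample(1:3, 1)
    a1 <- runif(n1, 1, 100); a2 <- runif(n2, 1, 100)
    b <- rnorm(d + 1, 0, c(1, 0.05, 0.005, 5e-5)[1:(d + 1)])
    y1 <- drop(outer(a1, 0:d, `^`) %*% b) + rnorm(n1, 0, runif(1, 0.3, 1.5))
    y2 <- drop(outer(a2, 0:d, `^`) %*% b) + rnorm(n2, 0, runif(1, 0.3, 1.5)) -
      runif(1, 0, 1)
    m1 <- fit_trajectory(a1, y1)
    m2 <- fit_trajectory(a2, y2)
    g <- seq(max(min(a1), min(a2)), min(max(a1), max(a2)), length.out = 25)
    b1 <- confidence_band(m1, g)
    b2 <- confidence_band(m2, g)
    nono <- b2$upr < b1$lwr | b2$lwr > b1$upr
    if (any(nono)) {
      tt <- abs(b1$fit - b2$fit) / sqrt(b1$se^2 + b2$se^2)
      df <- (b1$se^2 + b2$se^2)^2 /
        (b1$se^4 / m1$df_residual + b2$se^4 / m2$df_residual)
      violations <- violations + sum(nono & 2 * pt(-tt, df) >= 0.05)
    }
  }
  expect_identical(violations, 0)
})

test_that("steeper atrophy is detected no later", {
  set.seed(39)
  h <- function(a) 0.3 - 0.005 * a
  onsets <- sapply(c(0.05, 0.1, 0.2, 0.4), function(rate) {
    mean(sapply(1:4, function(r) {
      set.seed(100 * r)
      age_c <- runif(1500, 1, 100); age_p <- runif(60, 55, 86)
      z_c <- h(age_c) + rnorm(1500, 0, 0.8)
      z_p <- h(age_p) - rate * pmax(0, age_p - 62) + rnorm(60, 0, 0.8)
      hm <- fit_trajectory(age_c, z_c)
      keep <- age_c < min(age_p)
      dm <- fit_trajectory(c(age_c[keep], age_p), c(z_c[keep], z_p))
      d <- detect_divergence(hm, dm, seq(2, 86, 0.5))
      if (d$diverged && d$direction == "case_smaller") d$onset_age else NA
    }), na.rm = TRUE)
  })
  expect_lt(cor(c(0.05, 0.1, 0.2, 0.4), onsets, method = "spearman"), 0)
})
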