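# Independent oracles used across tests.

# Normal-equations OLS oracle: centers/scales ages itself, solves the
# 4x4 normal equations, and maps back to the raw-age basis by binomial
# expansion; shares no code path with fit_polynomial().
oracle_ols <- function(ages, values, degree) {
  mu <- mean(ages)
  sc <- stats::sd(ages)
  u <- (ages - mu) / sc
  Xu <- outer(u, 0:degree, `^`)
  A <- crossprod(Xu)
  bu <- solve(A, crossprod(Xu, values))
  Tm <- matrix(0, degree + 1, degree + 1)
  for (k in 0:degree) {
    for (j in 0:k) Tm[j + 1, k + 1] <- choose(k, j) * (-mu)^(k - j) / sc^k
  }
  beta <- drop(Tm %*% bu)
  n <- length(ages)
  p <- degree + 1
  res <- values - drop(outer(ages, 0:degree, `^`) %*% beta)
  rss <- sum(res^2)
  s2 <- rss / (n - p)
  V <- Tm %*% (solve(A) * s2) %*% t(Tm)
  se <- sqrt(diag(V))
  tstat <- beta / se
  pvals <- 2 * stats::pt(-abs(tstat), n - p)
  rss0 <- sum((values - mean(values))^2)
  f <- ((rss0 - rss) / degree) / (rss / (n - p))
  list(coef = beta, se = se, p = pvals, f_stat = f,
       f_p = stats::pf(f, degree, n - p, lower.tail = FALSE),
       rss = rss, bic = n * log(rss / n) + (degree + 2) * log(n),
       vcov = V, df = n - p)
}

max_rel_err <- function(a, b) max(abs(a - b) / pmax(abs(b), 1e-300))

# Brute-force recomputation of the band non-overlap criterion using lm()
# and predict.lm(); independent of the package's model/band code.
oracle_divergence_onset <- function(ages_h, z_h, ages_d, z_d, grid,
                                    level = 0.95) {
  pick <- function(a, z) {
    dat <- data.frame(a = a, z = z)
    fits <- lapply(1:3, function(d) {
      stats::lm(z ~ stats::poly(a, degree = d, raw = TRUE), data = dat)
    })
    ok <- vapply(fits, function(f) {
      s <- summary(f)
      f_p <- stats::pf(s$fstatistic[1], s$fstatistic[2], s$fstatistic[3],
                       lower.tail = FALSE)
      f_p < 0.05 && all(stats::coef(s)[-1, 4] < 0.05)
    }, logical(1))
    if (!any(ok)) return(stats::lm(z ~ 1, data = dat))
    bics <- vapply(seq_along(fits), function(i) {
      n <- nrow(dat)
      n * log(sum(stats::resid(fits[[i]])^2) / n) + (i + 2) * log(n)
    }, numeric(1))
    bics[!ok] <- Inf
    fits[[which.min(bics)]]
  }
  band <- function(fit, a) {
    pr <- stats::predict(fit, newdata = data.frame(a = a), se.fit = TRUE)
    tq <- stats::qt(1 - (1 - level) / 2, fit$df.residual)
    cbind(lwr = pr$fit - tq * pr$se.fit, upr = pr$fit + tq * pr$se.fit)
  }
  bh <- band(pick(ages_h, z_h), grid)
  bd <- band(pick(ages_d, z_d), grid)
  sep <- bd[, "upr"] < bh[, "lwr"]
  if (!any(sep) || !sep[length(sep)]) return(NA_real_)
  not_sep <- which(!sep)
  if (!length(not_sep)) grid[1L] else grid[max(not_sep) + 1L]
}
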