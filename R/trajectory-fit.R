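#' Fit one candidate polynomial lifespan model
#'
#' Ordinary least squares of z-scored volume on powers of age (raw-age
#' basis, intercept included). Reports per-coefficient two-sided t
#' tests, the F test against the intercept-only model, the residual sum
#' of squares, and the Gaussian-likelihood BIC
#' `n*log(rss/n) + k*log(n)` with `k = degree + 2` (coefficients plus
#' intercept plus residual variance). The candidate is `eligible` when
#' the F test and every non-intercept coefficient t test are significant
#' at `alpha` (set `gate_intercept = TRUE` to also require the
#' intercept, which on centred z-scores would spuriously reject flat
#' trajectories).
#'
#' @param ages ages in years; must have nonzero spread.
#' @param values z-scored normalized volumes, same length.
#' @param degree polynomial degree, 1, 2 or 3 (0 fits the constant
#'   model, used as the fallback).
#' @param alpha significance level of the eligibility gates.
#' @param gate_intercept include the intercept in the coefficient gate.
#' @return object of class `fit_candidate`: degree, coefficients
#'   (intercept first, raw-age basis), `se`, `p` (t tests), `f_stat`,
#'   `f_p`, `rss`, `n`, `k_params`, `bic`, `eligible`, `vcov`,
#'   `residual_sd`, `df_residual`, `age_range`.
#' @seealso [fit_trajectory()] which fits degrees 1-3 and selects by BIC
#' @export
#' @examples
#' age <- seq(1, 100, length.out = 60)
#' fit_polynomial(age, 1 + 2 * age, degree = 1)$coefficients
fit_polynomial <- function(ages, values, degree, alpha = 0.05,
                           gate_intercept = FALSE) {
  stopifnot(length(ages) == length(values), degree %in% 0:3)
  ok <- is.finite(ages) & is.finite(values)
  ages <- ages[ok]; values <- values[ok]
  n <- length(ages)
  if (n < degree + 2L) {
    stop(sprintf("need at least %d observations for degree %d, got %d",
                 degree + 2L, degree, n))
  }
  if (degree > 0L && stats::sd(ages) == 0) {
    stop("ages have zero spread; design is rank-deficient")
  }

  X <- outer(ages, 0:degree, `^`)
  colnames(X) <- c("(Intercept)",
                   if (degree >= 1L) paste0("age", ifelse(seq_len(degree) == 1L,
                     "", paste0("^", seq_len(degree)))))
  fit <- stats::lm.fit(X, values)
  if (fit$rank < ncol(X)) stop("rank-deficient design for degree ", degree)
  beta <- fit$coefficients
  res <- fit$residuals
  rss <- sum(res^2)
  p <- degree + 1L
  df_res <- n - p
  sigma2 <- rss / df_res
  XtXinv <- chol2inv(chol(crossprod(X)))
  vc <- sigma2 * XtXinv
  dimnames(vc) <- list(colnames(X), colnames(X))
  se <- sqrt(diag(vc))
  tstat <- beta / se
  pvals <- 2 * stats::pt(-abs(tstat), df_res)

  if (degree >= 1L) {
    rss0 <- sum((values - mean(values))^2)
    f_stat <- ((rss0 - rss) / degree) / (rss / df_res)
    f_p <- stats::pf(f_stat, degree, df_res, lower.tail = FALSE)
  } else {
    f_stat <- NA_real_; f_p <- NA_real_
  }

  k <- degree + 2L                       # coefficients + residual variance
  bic <- if (rss <= 0) -Inf else n * log(rss / n) + k * log(n)

  gate_p <- if (gate_intercept || degree == 0L) pvals else pvals[-1L]
  eligible <- degree >= 1L && is.finite(f_p) && f_p < alpha &&
    all(gate_p < alpha)

  structure(
    list(degree = degree, coefficients = beta, se = se, p = pvals,
         f_stat = f_stat, f_p = f_p, rss = rss, n = n, k_params = k,
         bic = bic, eligible = eligible, vcov = vc,
         residual_sd = sqrt(sigma2), df_residual = df_res,
         age_range = range(ages)),
    class = "fit_candidate")
}

#' @export
print.fit_candidate <- function(x, ...) {
  cat(sprintf("Polynomial candidate, degree %d (n = %d)\n", x$degree, x$n))
  print(round(rbind(estimate = x$coefficients, se = x$se, p = x$p), 6))
  cat(sprintf("F p = %.3g | RSS = %.4g | BIC = %.2f | eligible: %s\n",
              x$f_p, x$rss, x$bic, x$eligible))
  invisible(x)
}

#' Fit a lifespan trajectory with gated BIC model selection
#'
#' Fits linear, quadratic and cubic candidates (simplest to most
#' complex), keeps those whose F test against the constant model and
#' whose non-intercept coefficient t tests are all significant, and
#' selects the eligible candidate with the lowest BIC (ties broken
#' toward the lower degree). When no candidate is eligible, the
#' constant (degree 0) model is returned, flagged ineligible.
#'
#' @inheritParams fit_polynomial
#' @param degrees candidate degrees (default 1:3).
#' @param structure,group optional labels carried into results.
#' @return object of class `lifespan_fit` with the selected candidate's
#'   fields plus `candidates` (all fits), `structure`, `group` and the
#'   training data (`ages`, `values`).
#' @export
#' @examples
#' set.seed(1)
#' age <- runif(300, 1, 100)
#' z <- 0.5 + 0.04 * age - 6e-4 * age^2 + rnorm(300, 0, 0.5)
#' m <- fit_trajectory(age, z, structure = "thalamus", group = "control")
#' m$degree
#' predict(m, c(20, 60), interval = "confidence")
fit_trajectory <- function(ages, values, degrees = 1:3, alpha = 0.05,
                           gate_intercept = FALSE, structure = NA_character_,
                           group = NA_character_) {
  stopifnot(all(degrees %in% 1:3))
  degrees <- sort(unique(degrees))
  candidates <- lapply(degrees, function(d) {
    fit_polynomial(ages, values, d, alpha = alpha,
                   gate_intercept = gate_intercept)
  })
  names(candidates) <- paste0("degree", degrees)
  eligible <- vapply(candidates, `[[`, logical(1), "eligible")
  if (any(eligible)) {
    bics <- vapply(candidates, `[[`, numeric(1), "bic")
    bics[!eligible] <- Inf
    sel <- candidates[[which.min(bics)]]   # first minimum = lowest degree
  } else {
    sel <- fit_polynomial(ages, values, 0L, alpha = alpha)
  }
  ok <- is.finite(ages) & is.finite(values)
  structure(
    list(structure = structure, group = group, degree = sel$degree,
         selected = sel, candidates = candidates,
         coefficients = sel$coefficients, vcov = sel$vcov,
         n = sel$n, rss = sel$rss, bic = sel$bic,
         residual_sd = sel$residual_sd, df_residual = sel$df_residual,
         age_range = sel$age_range, eligible = sel$eligible,
         alpha = alpha, gate_intercept = gate_intercept,
         ages = ages[ok], values = values[ok]),
    class = "lifespan_fit")
}

#' @export
print.lifespan_fit <- function(x, ...) {
  lbl <- if (!is.na(x$structure)) paste0(" [", x$structure,
          if (!is.na(x$group)) paste0(", ", x$group), "]") else ""
  cat(sprintf("Lifespan trajectory%s: degree %d, n = %d, ages %.1f-%.1f\n",
              lbl, x$degree, x$n, x$age_range[1], x$age_range[2]))
  if (x$degree == 0L) cat("  (no candidate passed the significance gates; constant fallback)\n")
  cat("  coefficients:", paste(sprintf("%.4g", x$coefficients), collapse = ", "),
      "\n")
  cat(sprintf("  residual SD = %.3f, BIC = %.2f\n", x$residual_sd, x$bic))
  invisible(x)
}

#' @export
summary.lifespan_fit <- function(object, ...) {
  tab <- do.call(rbind, lapply(object$candidates, function(cd) {
    data.frame(degree = cd$degree, f_p = cd$f_p,
               max_coef_p = max(cd$p[-1L]), bic = cd$bic,
               eligible = cd$eligible)
  }))
  tab$selected <- tab$degree == object$degree
  structure(list(fit = object, candidates = tab),
            class = "summary.lifespan_fit")
}

#' @export
print.summary.lifespan_fit <- function(x, ...) {
  print(x$fit)
  cat("\nCandidate comparison:\n")
  print(x$candidates, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
coef.lifespan_fit <- function(object, ...) object$coefficients

#' @export
fitted.lifespan_fit <- function(object, ...) {
  predict(object, object$ages, extrapolate = Inf)
}

#' @export
residuals.lifespan_fit <- function(object, ...) {
  object$values - fitted(object)
}

#' Predict from a lifespan trajectory model
#'
#' @param object a [fit_trajectory()] model.
#' @param ages ages (years) at which to evaluate the curve.
#' @param interval `"none"`, `"confidence"` (pointwise band for the
#'   mean curve; the default elsewhere in the pipeline) or
#'   `"prediction"` (band for a new observation).
#' @param level confidence level.
#' @param extrapolate years beyond the training age range for which
#'   evaluation is still allowed (default 0); ages outside the window
#'   raise an error listing them.
#' @param ... unused.
#' @return numeric vector of fitted means, or a data.frame with
#'   `age`, `fit`, `se`, `lwr`, `upr` when an interval is requested.
#' @export
predict.lifespan_fit <- function(object, ages, interval = c("none",
                                 "confidence", "prediction"), level = 0.95,
                                 extrapolate = 0, ...) {
  interval <- match.arg(interval)
  lo <- object$age_range[1] - extrapolate
  hi <- object$age_range[2] + extrapolate
  bad <- ages < lo | ages > hi
  if (any(bad)) {
    stop("ages outside the allowed window [", signif(lo, 4), ", ",
         signif(hi, 4), "]: ", paste(signif(ages[bad], 4), collapse = ", "))
  }
  X <- outer(as.numeric(ages), 0:object$degree, `^`)
  fit <- drop(X %*% object$coefficients)
  if (interval == "none") return(fit)
  se_mean <- sqrt(pmax(0, rowSums((X %*% object$vcov) * X)))
  se <- if (interval == "confidence") se_mean else {
    sqrt(se_mean^2 + object$residual_sd^2)
  }
  tq <- stats::qt(1 - (1 - level) / 2, object$df_residual)
  data.frame(age = as.numeric(ages), fit = fit, se = se,
             lwr = fit - tq * se, upr = fit + tq * se)
}

#' Pointwise 95% band of a fitted trajectory on an age grid
#'
#' Convenience wrapper around [predict.lifespan_fit()]: the band is the
#' fitted mean plus/minus the t quantile times the standard error of the
#' fitted mean (mode `"confidence"`, the default) or of a new
#' observation (mode `"prediction"`).
#'
#' @param model a [fit_trajectory()] model.
#' @param grid age grid, years.
#' @param level confidence level (default 0.95).
#' @param mode `"confidence"` or `"prediction"`.
#' @param extrapolate allowed years beyond the training range.
#' @return data.frame with `age`, `fit`, `se`, `lwr`, `upr`.
#' @export
confidence_band <- function(model, grid, level = 0.95,
                            mode = c("confidence", "prediction"),
                            extrapolate = 0) {
  mode <- match.arg(mode)
  predict(model, grid, interval = mode, level = level,
          extrapolate = extrapolate)
}

#' Default evaluation grid of a fitted model
#'
#' Half-year steps spanning the training ages.
#'
#' @param model a [fit_trajectory()] model.
#' @param step grid step in years (default 0.5).
#' @return numeric vector of ages.
#' @export
age_grid <- function(model, step = 0.5) {
  seq(model$age_range[1], model$age_range[2], by = step)
}

#' @export
simulate.lifespan_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  mu <- fitted(object)
  out <- as.data.frame(replicate(nsim, mu +
    stats::rnorm(length(mu), 0, object$residual_sd), simplify = FALSE),
    col.names = paste0("sim_", seq_len(nsim)))
  attr(out, "ages") <- object$ages
  out
}

#' @export
plot.lifespan_fit <- function(x, level = 0.95, band = TRUE, ...) {
  grid <- age_grid(x)
  bd <- confidence_band(x, grid, level = level)
  graphics::plot(x$ages, x$values, pch = 16, cex = 0.4,
                 col = grDevices::grey(0.6), xlab = "age (years)",
                 ylab = "z-scored normalized volume",
                 main = paste0(x$structure %||% "", " ", x$group %||% ""),
                 ...)
  if (band) {
    graphics::polygon(c(bd$age, rev(bd$age)), c(bd$lwr, rev(bd$upr)),
                      col = grDevices::adjustcolor("steelblue", 0.3),
                      border = NA)
  }
  graphics::lines(bd$age, bd$fit, lwd = 2, col = "steelblue4")
  invisible(x)
}

#' Serialize fitted trajectory models to JSON
#'
#' Writes structure, group, degree, coefficients, covariance, sample
#' size, RSS, BIC and the gate outcomes for every model, so downstream
#' staging and plots are reproducible without refitting (see
#' [models_from_json()]).
#'
#' @param models list of [fit_trajectory()] models.
#' @param path output `.json` path.
#' @return `path`, invisibly.
#' @export
models_to_json <- function(models, path) {
  recs <- lapply(models, function(m) {
    list(structure = m$structure, group = m$group, degree = m$degree,
         coefficients = unname(m$coefficients), vcov = unname(m$vcov),
         n = m$n, rss = m$rss, bic = m$bic, residual_sd = m$residual_sd,
         df_residual = m$df_residual, age_range = m$age_range,
         eligible = m$eligible,
         candidate_bic = vapply(m$candidates, `[[`, numeric(1), "bic"),
         candidate_eligible = vapply(m$candidates, `[[`, logical(1),
                                     "eligible"))
  })
  writeLines(jsonlite::toJSON(recs, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE, na = "null"), path)
  invisible(path)
}

#' Rebuild trajectory models from their JSON serialization
#'
#' The rebuilt objects support [predict.lifespan_fit()],
#' [confidence_band()] and all downstream divergence/staging steps;
#' training data (hence residuals/refitting) are not stored.
#'
#' @param path a file written by [models_to_json()].
#' @return list of `lifespan_fit` objects.
#' @export
models_from_json <- function(path) {
  recs <- jsonlite::read_json(path, simplifyVector = TRUE,
                              simplifyDataFrame = FALSE)
  lapply(recs, function(r) {
    vc <- matrix(unlist(r$vcov), nrow = r$degree + 1L)
    structure(
      list(structure = r$structure, group = r$group, degree = r$degree,
           coefficients = unlist(r$coefficients), vcov = vc, n = r$n,
           rss = r$rss, bic = r$bic, residual_sd = r$residual_sd,
           df_residual = r$df_residual, age_range = unlist(r$age_range),
           eligible = r$eligible, candidates = NULL,
           ages = numeric(), values = numeric()),
      class = "lifespan_fit")
  })
}
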