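#' Signed distance between healthy and disease trajectory means
#'
#' `healthy_mean(age) - disease_mean(age)` in z-units at each grid age;
#' positive values mean the disease trajectory lies below (smaller
#' volume than) the healthy one.
#'
#' @param healthy,disease [fit_trajectory()] models of the same
#'   structure (fitted on z-scores sharing the reference statistics).
#' @param grid age grid, years.
#' @param extrapolate allowed years beyond each model's training range.
#' @return data.frame with `age`, `healthy`, `disease`, `distance`.
#' @export
distance_curve <- function(healthy, disease, grid, extrapolate = 5) {
  .check_same_structure(healthy, disease)
  h <- predict(healthy, grid, extrapolate = extrapolate)
  d <- predict(disease, grid, extrapolate = extrapolate)
  data.frame(age = as.numeric(grid), healthy = h, disease = d,
             distance = h - d)
}

#' Distance between model means at a reference age
#'
#' The severity / effect-size score used to rank structures: the signed
#' difference of the two fitted means (z-units) at `ref_age` (90 years
#' by default), evaluated on the model means, not on the bands.
#'
#' @inheritParams distance_curve
#' @param ref_age reference age, years; must lie within the allowed
#'   evaluation window of both models.
#' @return signed distance in z-units.
#' @export
distance_at_reference <- function(healthy, disease, ref_age = 90,
                                  extrapolate = 5) {
  .check_same_structure(healthy, disease)
  predict(healthy, ref_age, extrapolate = extrapolate) -
    predict(disease, ref_age, extrapolate = extrapolate)
}

.check_same_structure <- function(healthy, disease) {
  if (!is.na(healthy$structure) && !is.na(disease$structure) &&
      healthy$structure != disease$structure) {
    stop("models are for different structures: '", healthy$structure,
         "' vs '", disease$structure, "'")
  }
  invisible(TRUE)
}

#' Detect the age at which two trajectories significantly diverge
#'
#' A structure is declared significantly smaller in the disease group
#' when the two trajectories diverge and their 95% bands no longer
#' overlap. With the default `"sustained"` rule the onset is the
#' smallest grid age from which the disease upper bound stays strictly
#' below the healthy lower bound through the end of the grid (transient
#' early band crossings are treated as noise); `"first"` reports the
#' first instantaneous non-overlap instead. The opposite direction
#' (disease above healthy) is detected analogously and reported as an
#' anomaly — it never enters atrophy staging.
#'
#' @inheritParams distance_curve
#' @param level band confidence level (default 0.95).
#' @param rule `"sustained"` (default) or `"first"`.
#' @param band_mode `"confidence"` (bands for the mean curve, default)
#'   or `"prediction"` (new-observation bands).
#' @param ref_age reference age for the severity score.
#' @return object of class `divergence_result`: `structure`,
#'   `diverged`, `onset_age` (grid precision, `NA` when not diverged),
#'   `direction` (`"case_smaller"`, `"case_larger"` or `"none"`),
#'   `distance_at_ref`, `ref_age`, and `curve` (data.frame with the
#'   distance curve and both bands on the grid).
#' @export
detect_divergence <- function(healthy, disease, grid, level = 0.95,
                              rule = c("sustained", "first"),
                              band_mode = c("confidence", "prediction"),
                              extrapolate = 5, ref_age = 90) {
  rule <- match.arg(rule)
  band_mode <- match.arg(band_mode)
  .check_same_structure(healthy, disease)
  grid <- as.numeric(grid)
  if (length(grid) < 2L || is.unsorted(grid)) {
    stop("'grid' must be an increasing age grid")
  }
  hb <- confidence_band(healthy, grid, level = level, mode = band_mode,
                        extrapolate = extrapolate)
  db <- confidence_band(disease, grid, level = level, mode = band_mode,
                        extrapolate = extrapolate)
  sep_smaller <- db$upr < hb$lwr      # disease entirely below healthy
  sep_larger <- db$lwr > hb$upr

  onset_from <- function(sep) {
    if (!any(sep)) return(NA_real_)
    if (rule == "first") return(grid[which(sep)[1L]])
    if (!sep[length(sep)]) return(NA_real_)      # not separated at grid end
    not_sep <- which(!sep)
    if (!length(not_sep)) grid[1L] else grid[max(not_sep) + 1L]
  }
  onset_s <- onset_from(sep_smaller)
  onset_l <- onset_from(sep_larger)
  if (!is.na(onset_s)) {
    direction <- "case_smaller"; onset <- onset_s
  } else if (!is.na(onset_l)) {
    direction <- "case_larger"; onset <- onset_l
  } else {
    direction <- "none"; onset <- NA_real_
  }

  # severity score; the reference age may exceed the grid by at most the
  # models' extrapolation allowance (it typically exceeds the oldest
  # patient), otherwise predict() rejects it with the offending age
  dref <- distance_at_reference(healthy, disease, ref_age,
                                extrapolate = extrapolate)

  curve <- data.frame(age = grid, distance = hb$fit - db$fit,
                      healthy_fit = hb$fit, healthy_lwr = hb$lwr,
                      healthy_upr = hb$upr, disease_fit = db$fit,
                      disease_lwr = db$lwr, disease_upr = db$upr,
                      separated = sep_smaller | sep_larger)
  structure(
    list(structure = healthy$structure %||% disease$structure,
         diverged = direction != "none", onset_age = onset,
         direction = direction, distance_at_ref = dref, ref_age = ref_age,
         level = level, rule = rule, band_mode = band_mode, curve = curve),
    class = "divergence_result")
}

#' @export
print.divergence_result <- function(x, ...) {
  cat(sprintf("Divergence [%s]: %s", x$structure %||% "?",
              if (x$diverged) sprintf("onset %.1f y (%s)", x$onset_age,
                                      x$direction) else "none"))
  cat(sprintf("; distance at %g y = %.2f z\n", x$ref_age, x$distance_at_ref))
  invisible(x)
}

#' Run divergence detection for every structure
#'
#' @param healthy_models,disease_models named lists of
#'   [fit_trajectory()] models, indexed by structure; names must match.
#' @inheritParams detect_divergence
#' @return named list of `divergence_result` objects.
#' @export
detect_divergence_all <- function(healthy_models, disease_models, grid, ...) {
  structures <- names(healthy_models)
  if (!setequal(structures, names(disease_models))) {
    stop("healthy and disease model lists cover different structures")
  }
  out <- lapply(structures, function(s) {
    detect_divergence(healthy_models[[s]], disease_models[[s]], grid, ...)
  })
  names(out) <- structures
  out
}

#' Tabulate divergence results
#'
#' @param results list of `divergence_result` objects.
#' @return data.frame with one row per structure: `structure`,
#'   `diverged`, `onset_age`, `distance_at_ref`, `direction`.
#' @export
divergence_table <- function(results) {
  do.call(rbind, lapply(results, function(r) {
    data.frame(structure = r$structure, diverged = r$diverged,
               onset_age = r$onset_age, distance_at_ref = r$distance_at_ref,
               direction = r$direction, stringsAsFactors = FALSE,
               row.names = NULL)
  }))
}
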