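#' Preprocess a subject table into per-structure z-score series
#'
#' Left/right hemisphere columns are summed, raw volumes are normalized
#' to TIV (% of total intracranial volume), and each structure is
#' z-scored against the control sample (the whole-lifespan healthy
#' reference), so all structures share one interpretable scale. The
#' Kolmogorov-Smirnov normality of each structure's control normalized
#' volumes is recorded (flag only; nothing is excluded).
#'
#' @param subjects subject table (see [read_subject_table()]).
#' @param metadata optional structure metadata
#'   ([read_structure_metadata()]) used to validate the hemisphere
#'   pairing; auto-detection from `_L`/`_R` suffixes otherwise.
#' @return list with `series` (named list of [structure_series()]),
#'   `ks` (per-structure normality data.frame) and `subjects` (the
#'   combined, normalized table).
#' @export
preprocess_subjects <- function(subjects, metadata = NULL) {
  validate_subject_table(subjects)
  sym <- if (!is.null(metadata)) {
    intersect(metadata$symmetric,
              unique(sub("_[LR]$", "", .structure_columns(subjects))))
  }
  comb <- combine_lr(subjects, symmetric = sym)
  structures <- .structure_columns(comb)
  is_control <- comb$group == "control"
  series <- list()
  ks_rows <- list()
  for (s in structures) {
    norm <- normalize_to_tiv(comb[[s]], comb$tiv_mm3)
    ref <- norm[is_control]
    zs <- zscore(norm, ref)
    series[[s]] <- structure_series(s, comb$age, zs$z, comb$group,
                                    zs$ref_mean, zs$ref_sd)
    kt <- ks_normality(ref)
    ks_rows[[s]] <- data.frame(structure = s, statistic = kt$statistic,
                               p_value = kt$p_value, reject = kt$reject,
                               status = kt$status, n = kt$n)
    comb[[s]] <- norm
  }
  ks <- do.call(rbind, ks_rows)
  rownames(ks) <- NULL
  list(series = series, ks = ks, subjects = comb)
}

#' Run the full staging pipeline on a subject table
#'
#' Preprocessing (left/right summation, TIV normalization, z-scoring,
#' KS normality flags), healthy and lifespan-constrained disease
#' trajectory fits with gated BIC selection, model-outlier flagging,
#' band non-overlap divergence detection, and chronological staging.
#' The disease training set combines all cases with the controls
#' strictly younger than the youngest case, anchoring the disease model
#' over the whole lifespan.
#'
#' @param subjects subject table (data.frame or CSV/TSV path).
#' @param metadata structure metadata; default
#'   [default_structure_metadata()] when its groupings apply, else
#'   `NULL` for auto-detection with per-structure groups.
#' @param grid_step divergence grid step, years (default 0.5).
#' @param ref_age severity reference age (default 90).
#' @param level band confidence level (default 0.95).
#' @param band_mode `"confidence"` (default) or `"prediction"`.
#' @param rule `"sustained"` (default) or `"first"` non-overlap rule.
#' @param extrapolate years beyond each model's training ages over
#'   which bands may be evaluated (default 5; the reference age
#'   typically exceeds the oldest patient).
#' @param gap_threshold staging gap threshold, years (default 2).
#' @param degrees candidate polynomial degrees (default 1:3).
#' @param alpha significance level of the eligibility gates.
#' @param gate_intercept include the intercept in the coefficient gate.
#' @param seed optional seed recorded in the manifest (the pipeline
#'   itself is deterministic).
#' @return object of class `staging_run`: config, preprocessing report
#'   (`ks`, `outliers`), fitted `models` (healthy/disease per
#'   structure), `divergence` results and table, the `scheme`, the
#'   severity ranking, and a `manifest`.
#' @export
stage_cohort <- function(subjects, metadata = NULL, grid_step = 0.5,
                         ref_age = 90, level = 0.95,
                         band_mode = c("confidence", "prediction"),
                         rule = c("sustained", "first"), extrapolate = 5,
                         gap_threshold = 2, degrees = 1:3, alpha = 0.05,
                         gate_intercept = FALSE, seed = NULL) {
  band_mode <- match.arg(band_mode)
  rule <- match.arg(rule)
  if (is.character(subjects)) subjects <- read_subject_table(subjects)

  prep <- preprocess_subjects(subjects, metadata)
  controls_idx <- prep$subjects$group == "control"
  cases_idx <- prep$subjects$group == "case"
  if (!any(cases_idx)) stop("no case subjects in the input table")
  youngest_case <- min(prep$subjects$age[cases_idx])
  disease_idx <- cases_idx | (controls_idx &
                                prep$subjects$age < youngest_case)

  healthy_models <- list()
  disease_models <- list()
  outlier_rows <- list()
  fallback <- character()
  for (s in names(prep$series)) {
    ser <- prep$series[[s]]
    hm <- fit_trajectory(ser$ages[controls_idx], ser$values[controls_idx],
                         degrees = degrees, alpha = alpha,
                         gate_intercept = gate_intercept,
                         structure = s, group = "control")
    dm <- fit_trajectory(ser$ages[disease_idx], ser$values[disease_idx],
                         degrees = degrees, alpha = alpha,
                         gate_intercept = gate_intercept,
                         structure = s, group = "case")
    healthy_models[[s]] <- hm
    disease_models[[s]] <- dm
    if (hm$degree == 0L) fallback <- c(fallback, paste0(s, "/control"))
    if (dm$degree == 0L) fallback <- c(fallback, paste0(s, "/case"))
    outlier_rows[[s]] <- data.frame(
      structure = s,
      n_outliers_control = sum(flag_model_outliers(
        ser$ages[controls_idx], ser$values[controls_idx], hm)),
      n_outliers_disease = sum(flag_model_outliers(
        ser$ages[disease_idx], ser$values[disease_idx], dm)))
  }
  outliers <- do.call(rbind, outlier_rows)
  rownames(outliers) <- NULL

  grid_lo <- max(min(prep$subjects$age[controls_idx]),
                 min(prep$subjects$age[disease_idx]))
  oldest_common <- min(max(prep$subjects$age[controls_idx]),
                       max(prep$subjects$age[disease_idx]))
  # non-overlap is decided on the age range both models support; only
  # the severity score at ref_age may require extrapolation beyond the
  # oldest patient
  extrapolate_eff <- max(extrapolate, ref_age - oldest_common)
  grid <- seq(ceiling(grid_lo / grid_step) * grid_step, oldest_common,
              by = grid_step)

  divergence <- detect_divergence_all(
    healthy_models, disease_models, grid, level = level, rule = rule,
    band_mode = band_mode, extrapolate = extrapolate_eff, ref_age = ref_age)
  div_tab <- divergence_table(divergence)

  grouping_map <- if (!is.null(metadata) &&
                        length(metadata$grouping_map)) {
    gm <- metadata$grouping_map
    extra <- setdiff(names(prep$series), names(gm))
    gm[extra] <- extra                  # unmapped structures: own group
    gm
  }
  scheme <- staging_scheme(divergence, grouping_map = grouping_map,
                           gap_threshold = gap_threshold)
  severity <- rank_severity(div_tab)

  config <- list(grid_step = grid_step, ref_age = ref_age, level = level,
                 band_mode = band_mode, rule = rule,
                 extrapolate = extrapolate, gap_threshold = gap_threshold,
                 degrees = degrees, alpha = alpha,
                 gate_intercept = gate_intercept, seed = seed)
  manifest <- list(
    package_version = as.character(utils::packageVersion("brainchart")),
    r_version = R.version.string,
    config = config,
    n_subjects = nrow(prep$subjects),
    n_controls = sum(controls_idx),
    n_cases = sum(cases_idx),
    n_disease_training = sum(disease_idx),
    youngest_case_age = youngest_case,
    structures = names(prep$series),
    ks_failures = prep$ks$structure[prep$ks$reject %in% TRUE],
    fallback_models = fallback,
    case_larger_anomalies =
      div_tab$structure[div_tab$direction == "case_larger"])

  structure(
    list(config = config, ks = prep$ks, outliers = outliers,
         models = list(healthy = healthy_models, disease = disease_models),
         divergence = divergence, divergence_table = div_tab,
         scheme = scheme, severity = severity, grid = grid,
         manifest = manifest),
    class = "staging_run")
}

#' @export
print.staging_run <- function(x, ...) {
  m <- x$manifest
  cat(sprintf("Staging run: %d subjects (%d controls, %d cases), %d structures\n",
              m$n_subjects, m$n_controls, m$n_cases, length(m$structures)))
  cat(sprintf("  disease model constrained over the lifespan with %d records (controls < %.1f y + cases)\n",
              m$n_disease_training, m$youngest_case_age))
  nd <- sum(x$divergence_table$diverged &
              x$divergence_table$direction == "case_smaller")
  cat(sprintf("  %d of %d structures diverged (case smaller)\n",
              nd, nrow(x$divergence_table)))
  if (length(m$case_larger_anomalies)) {
    cat("  anomalies (case larger):",
        paste(m$case_larger_anomalies, collapse = ", "), "\n")
  }
  if (length(m$fallback_models)) {
    cat("  constant fallbacks:", paste(m$fallback_models, collapse = ", "),
        "\n")
  }
  print(x$scheme)
  invisible(x)
}

#' Write a staging run to a directory
#'
#' Fixed file names: `models.json`, `divergence.csv`, `staging.csv`,
#' `staging.json`, `ks_report.csv`, `outliers.csv`, `report.md`,
#' `manifest.json`. Output contains no timestamps, so a rerun on the
#' same inputs and configuration is byte-identical.
#'
#' @param run a [stage_cohort()] result.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_staging_run <- function(run, dir) {
  stopifnot(inherits(run, "staging_run"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  models_to_json(c(run$models$healthy, run$models$disease),
                 file.path(dir, "models.json"))
  utils::write.csv(run$divergence_table, file.path(dir, "divergence.csv"),
                   row.names = FALSE)
  utils::write.csv(run$scheme$entries, file.path(dir, "staging.csv"),
                   row.names = FALSE)
  writeLines(jsonlite::toJSON(
    list(entries = run$scheme$entries,
         gap_threshold = run$scheme$gap_threshold,
         grouping_map = as.list(run$scheme$grouping_map)),
    auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null"),
    file.path(dir, "staging.json"))
  utils::write.csv(run$ks, file.path(dir, "ks_report.csv"),
                   row.names = FALSE)
  utils::write.csv(run$outliers, file.path(dir, "outliers.csv"),
                   row.names = FALSE)

  cfg_json <- jsonlite::toJSON(run$config, auto_unbox = TRUE, digits = NA,
                               na = "null")
  tf <- tempfile(); writeLines(cfg_json, tf)
  manifest <- run$manifest
  manifest$config_hash <- unname(tools::md5sum(tf))
  unlink(tf)
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE, na = "null"),
             file.path(dir, "manifest.json"))

  rep <- c(
    "# Staging run report", "",
    sprintf("- subjects: %d (%d controls, %d cases)", manifest$n_subjects,
            manifest$n_controls, manifest$n_cases),
    sprintf("- disease training set: %d records (controls younger than %.2f y plus cases)",
            manifest$n_disease_training, manifest$youngest_case_age),
    sprintf("- structures analysed: %d", length(manifest$structures)),
    sprintf("- diverged (case smaller): %d",
            sum(run$divergence_table$diverged &
                  run$divergence_table$direction == "case_smaller")),
    sprintf("- KS normality flags: %s",
            if (any(run$ks$reject %in% TRUE))
              paste(run$ks$structure[run$ks$reject %in% TRUE],
                    collapse = ", ") else "none"),
    sprintf("- constant-model fallbacks: %s",
            if (length(manifest$fallback_models))
              paste(manifest$fallback_models, collapse = ", ") else "none"),
    sprintf("- case-larger anomalies: %s",
            if (length(manifest$case_larger_anomalies))
              paste(manifest$case_larger_anomalies, collapse = ", ")
            else "none"),
    "", "## Staging timeline", "")
  e <- run$scheme$entries
  if (nrow(e)) {
    rep <- c(rep, sprintf("%d. stage %d: %s — onset %.1f y, distance at %g y = %.2f z",
                          seq_len(nrow(e)), e$stage_index, e$structure,
                          e$onset_age, run$config$ref_age,
                          e$distance_at_ref))
  } else {
    rep <- c(rep, "no diverging structures")
  }
  writeLines(rep, file.path(dir, "report.md"))
  invisible(dir)
}

#' Simulate a cohort and write it to disk
#'
#' Writes `subjects.csv`, `truth.csv` and `manifest.json` (seed,
#' package and R versions) to `dir`; rerunning with the same arguments
#' reproduces the files byte for byte.
#'
#' @inheritParams simulate_cohort
#' @param dir output directory.
#' @return the [simulate_cohort()] object, invisibly.
#' @export
simulate_cohort_files <- function(specs, truths, seed, dir) {
  sim <- simulate_cohort(specs, truths, seed)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_subject_table(sim$subjects, file.path(dir, "subjects.csv"))
  utils::write.csv(.format_full_precision(sim$truth),
                   file.path(dir, "truth.csv"), row.names = FALSE,
                   quote = FALSE)
  writeLines(jsonlite::toJSON(
    list(seed = sim$seed, n_subjects = nrow(sim$subjects),
         n_clamped = sim$n_clamped,
         package_version = as.character(utils::packageVersion("brainchart")),
         r_version = R.version.string),
    auto_unbox = TRUE, digits = NA, pretty = TRUE),
    file.path(dir, "manifest.json"))
  invisible(sim)
}

#' Parameter-recovery study against known simulation truth
#'
#' For each seed, simulates a cohort, runs the full staging pipeline,
#' and compares estimated divergence onsets with the generator's truth:
#' per-structure onset error, per-seed Kendall tau between recovered
#' and true onset ordering (over detected structures), and detection
#' counts.
#'
#' @param scenario list with `specs` and `truths` (see
#'   [recovery_scenario()]).
#' @param seeds integer vector of simulation seeds.
#' @param ... passed to [stage_cohort()].
#' @return object of class `recovery_report`: `per_structure`
#'   (data.frame: seed, structure, true/estimated onset, error),
#'   `per_seed` (data.frame: seed, kendall_tau, n_detected,
#'   median_abs_error), and `summary` (medians/rates across seeds).
#' @export
recover_parameters <- function(scenario, seeds = 1:5, ...) {
  truth <- truth_table(scenario$truths)
  per_structure <- list()
  per_seed <- list()
  for (sd in seeds) {
    sim <- simulate_cohort(scenario$specs, scenario$truths, seed = sd)
    run <- stage_cohort(sim$subjects, seed = sd, ...)
    est <- run$divergence_table
    if (!setequal(est$structure, truth$structure)) {
      stop("structure names in estimates and truth do not match")
    }
    m <- merge(truth[, c("structure", "onset_age")], est,
               by = "structure", suffixes = c("_true", "_est"))
    m$onset_error <- m$onset_age_est - m$onset_age_true
    per_structure[[as.character(sd)]] <-
      data.frame(seed = sd, structure = m$structure,
                 onset_true = m$onset_age_true, onset_est = m$onset_age_est,
                 onset_error = m$onset_error, detected = m$diverged &
                   m$direction == "case_smaller")
    det <- m[m$diverged & m$direction == "case_smaller" &
               !is.na(m$onset_age_true), , drop = FALSE]
    tau <- if (nrow(det) >= 2L) {
      suppressWarnings(stats::cor(det$onset_age_true, det$onset_age_est,
                                  method = "kendall"))
    } else NA_real_
    per_seed[[as.character(sd)]] <- data.frame(
      seed = sd, kendall_tau = tau, n_detected = nrow(det),
      n_true_diverging = sum(!is.na(truth$onset_age)),
      median_abs_error = stats::median(abs(det$onset_error)))
  }
  per_structure <- do.call(rbind, per_structure)
  per_seed <- do.call(rbind, per_seed)
  rownames(per_structure) <- rownames(per_seed) <- NULL
  det_all <- per_structure[per_structure$detected &
                             !is.na(per_structure$onset_true), ]
  summary <- list(
    median_abs_onset_error = stats::median(abs(det_all$onset_error)),
    tau_values = per_seed$kendall_tau,
    prop_tau_ge_0.8 = mean(per_seed$kendall_tau >= 0.8, na.rm = TRUE),
    mean_detected = mean(per_seed$n_detected))
  structure(list(per_structure = per_structure, per_seed = per_seed,
                 summary = summary),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf("Recovery over %d seeds: median |onset error| = %.2f y; tau >= 0.8 in %.0f%% of seeds; %.1f structures detected on average\n",
              nrow(x$per_seed), s$median_abs_onset_error,
              100 * s$prop_tau_ge_0.8, s$mean_detected))
  invisible(x)
}
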