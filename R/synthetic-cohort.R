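#' Ground-truth lifespan trajectory for one simulated brain structure
#'
#' Encodes everything the cohort simulator needs for one structure: the
#' healthy lifespan polynomial (in z-units of the TIV-normalized volume),
#' the disease deviation kinetics (a piecewise-linear hinge: cases follow
#' the healthy curve until `onset_age`, then fall below it by
#' `deviation_rate` z-units per year), observation noise, the left/right
#' split, and the reference statistics that map z-units back to
#' normalized volume (% of total intracranial volume) so the simulator
#' can emit raw volumes in mm3.
#'
#' @param structure structure name (used as the output column stem).
#' @param healthy_coeffs numeric, intercept-first polynomial coefficients
#'   of the healthy z trajectory versus age in years; degree at most 3.
#' @param noise_sd additive Gaussian observation noise, z-units; must be
#'   positive.
#' @param onset_age age (years) at which case trajectories start to
#'   deviate; `NA` marks a non-diverging structure.
#' @param deviation_rate z-units lost per year after onset; non-negative.
#' @param lr_split fraction of the total volume assigned to the left
#'   hemisphere (strictly between 0 and 1), or `NA` for a midline
#'   structure emitted as a single column.
#' @param ref_mean,ref_sd mean and sd of the normalized volume (% of
#'   TIV) that define the z scale; both positive.
#' @return an object of class `trajectory_truth` (a named list).
#' @seealso [simulate_cohort()], [truth_table()]
#' @export
#' @examples
#' trajectory_truth("thalamus", c(0.5, 0.01, -2e-4),
#'                  onset_age = 65, deviation_rate = 0.16,
#'                  ref_mean = 1.06, ref_sd = 0.09)
trajectory_truth <- function(structure, healthy_coeffs, noise_sd = 0.8,
                             onset_age = NA_real_, deviation_rate = 0,
                             lr_split = 0.5, ref_mean = 1, ref_sd = 0.1) {
  stopifnot(is.character(structure), length(structure) == 1L, nzchar(structure))
  if (!is.numeric(healthy_coeffs) || length(healthy_coeffs) < 1L ||
      length(healthy_coeffs) > 4L) {
    stop("'healthy_coeffs' must be 1 to 4 numbers (degree <= 3)")
  }
  if (!is.na(onset_age) && (!is.numeric(onset_age) || onset_age < 0)) {
    stop("'onset_age' must be a non-negative age in years, or NA")
  }
  if (deviation_rate < 0) stop("'deviation_rate' must be >= 0")
  if (noise_sd <= 0) stop("'noise_sd' must be > 0")
  if (ref_mean <= 0 || ref_sd <= 0) stop("'ref_mean' and 'ref_sd' must be > 0")
  if (!is.na(lr_split) && (lr_split <= 0 || lr_split >= 1)) {
    stop("'lr_split' must lie strictly between 0 and 1, or be NA (midline)")
  }
  structure(
    list(structure = structure,
         healthy_coeffs = as.numeric(healthy_coeffs),
         onset_age = as.numeric(onset_age),
         deviation_rate = as.numeric(deviation_rate),
         noise_sd = as.numeric(noise_sd),
         lr_split = as.numeric(lr_split),
         ref_mean = as.numeric(ref_mean),
         ref_sd = as.numeric(ref_sd)),
    class = "trajectory_truth")
}

#' Specification of one simulated cohort
#'
#' Cohorts mimic the heterogeneous multi-study design of lifespan brain
#' charts: each contributes subjects of one group over its own age
#' window, with its own intracranial-volume distribution.
#'
#' @param cohort_id cohort label.
#' @param group `"control"` or `"case"`.
#' @param n_subjects number of subjects (>= 1).
#' @param age_range length-2 numeric, years; ages are drawn uniformly
#'   within it.
#' @param tiv_mean,tiv_sd normal law of total intracranial volume, mm3
#'   (truncated at zero by resampling).
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(cohort_id, group, n_subjects, age_range,
                        tiv_mean = 1.45e6, tiv_sd = 1.2e5) {
  group <- match.arg(group, c("control", "case"))
  stopifnot(length(age_range) == 2L, is.numeric(age_range))
  if (n_subjects < 1) stop("'n_subjects' must be >= 1")
  if (age_range[1] >= age_range[2]) stop("'age_range' must satisfy min < max")
  if (tiv_mean <= 0) stop("'tiv_mean' must be > 0")
  structure(
    list(cohort_id = as.character(cohort_id), group = group,
         n_subjects = as.integer(n_subjects),
         age_range = as.numeric(age_range),
         tiv_mean = as.numeric(tiv_mean), tiv_sd = as.numeric(tiv_sd)),
    class = "cohort_spec")
}

#' Truth table for a list of trajectory truths
#'
#' One row per structure, echoing every ground-truth parameter
#' (polynomial coefficients padded to degree 3 as `c0`..`c3`).
#'
#' @param truths list of [trajectory_truth()] objects.
#' @return a data.frame.
#' @export
truth_table <- function(truths) {
  stopifnot(length(truths) >= 1L)
  rows <- lapply(truths, function(tr) {
    stopifnot(inherits(tr, "trajectory_truth"))
    cf <- c(tr$healthy_coeffs, rep(0, 4L - length(tr$healthy_coeffs)))
    data.frame(structure = tr$structure,
               c0 = cf[1], c1 = cf[2], c2 = cf[3], c3 = cf[4],
               onset_age = tr$onset_age,
               deviation_rate = tr$deviation_rate,
               noise_sd = tr$noise_sd,
               lr_split = tr$lr_split,
               ref_mean = tr$ref_mean,
               ref_sd = tr$ref_sd)
  })
  do.call(rbind, rows)
}

#' Simulate a multi-cohort cross-sectional volumetric dataset
#'
#' Generates one subject table with known ground truth. For each subject
#' the z-scored trajectory value is
#' `healthy(age) - deviation_rate * max(0, age - onset_age)` (the hinge
#' applying to cases only) plus Gaussian noise; it is mapped to a
#' normalized volume through the structure's reference statistics,
#' multiplied by the subject's TIV to give a raw volume in mm3, and
#' split into left/right hemisphere columns where the structure is
#' symmetric. Output is fully determined by `(specs, truths, seed)`.
#'
#' @param specs list of [cohort_spec()] objects (non-empty).
#' @param truths list of [trajectory_truth()] objects with unique
#'   structure names (non-empty).
#' @param seed integer seed; required for reproducibility.
#' @return an object of class `cohort_sim`: a list with elements
#'   `subjects` (data.frame: subject_id, cohort_id, group, sex, age,
#'   tiv_mm3, then one column per structure or hemisphere, e.g.
#'   `thalamus_L`, `thalamus_R`, `brainstem`), `truth` (the
#'   [truth_table()]), and `n_clamped` (count of raw volumes clamped at
#'   the positive floor).
#' @export
#' @examples
#' sim <- simulate_cohort(
#'   list(cohort_spec("HC", "control", 50, c(1, 100)),
#'        cohort_spec("PSP", "case", 10, c(55, 86))),
#'   list(trajectory_truth("thalamus", c(0.5, -0.01),
#'                         onset_age = 60, deviation_rate = 0.1,
#'                         ref_mean = 1.06, ref_sd = 0.09)),
#'   seed = 1)
#' head(sim$subjects)
simulate_cohort <- function(specs, truths, seed) {
  if (length(specs) < 1L) stop("'specs' must be non-empty")
  if (length(truths) < 1L) stop("'truths' must be non-empty")
  stopifnot(all(vapply(specs, inherits, logical(1), "cohort_spec")),
            all(vapply(truths, inherits, logical(1), "trajectory_truth")))
  snames <- vapply(truths, `[[`, character(1), "structure")
  if (anyDuplicated(snames)) stop("structure names must be unique")
  if (missing(seed) || !is.numeric(seed)) stop("an integer 'seed' is required")
  set.seed(as.integer(seed))

  demo <- do.call(rbind, lapply(seq_along(specs), function(i) {
    sp <- specs[[i]]
    n <- sp$n_subjects
    age <- stats::runif(n, sp$age_range[1], sp$age_range[2])
    tiv <- stats::rnorm(n, sp$tiv_mean, sp$tiv_sd)
    while (any(bad <- tiv <= 0)) {                   # truncate at zero
      tiv[bad] <- stats::rnorm(sum(bad), sp$tiv_mean, sp$tiv_sd)
    }
    data.frame(subject_id = sprintf("%s_%04d", sp$cohort_id, seq_len(n)),
               cohort_id = sp$cohort_id, group = sp$group,
               sex = sample(c("F", "M"), n, replace = TRUE),
               age = age, tiv_mm3 = tiv)
  }))
  rownames(demo) <- NULL

  n_clamped <- 0L
  floor_mm3 <- 1
  vols <- list()
  is_case <- demo$group == "case"
  for (tr in truths) {
    z <- eval_poly(tr$healthy_coeffs, demo$age)
    if (!is.na(tr$onset_age) && tr$deviation_rate > 0) {
      z <- z - ifelse(is_case,
                      tr$deviation_rate * pmax(0, demo$age - tr$onset_age), 0)
    }
    z <- z + stats::rnorm(nrow(demo), 0, tr$noise_sd)
    norm_pct <- tr$ref_mean + tr$ref_sd * z
    total <- norm_pct / 100 * demo$tiv_mm3
    clamped <- total < floor_mm3
    n_clamped <- n_clamped + sum(clamped)
    total[clamped] <- floor_mm3
    if (is.na(tr$lr_split)) {
      vols[[tr$structure]] <- total
    } else {
      vols[[paste0(tr$structure, "_L")]] <- total * tr$lr_split
      vols[[paste0(tr$structure, "_R")]] <- total * (1 - tr$lr_split)
    }
  }
  if (n_clamped > 0L) {
    warning(sprintf("%d raw volumes clamped at the %g mm3 floor",
                    n_clamped, floor_mm3))
  }
  subjects <- cbind(demo, as.data.frame(vols, check.names = FALSE))
  structure(list(subjects = subjects, truth = truth_table(truths),
                 n_clamped = n_clamped, seed = as.integer(seed)),
            class = "cohort_sim")
}

#' @export
print.cohort_sim <- function(x, ...) {
  cat(sprintf("Simulated cohort: %d subjects (%d controls, %d cases), %d structures\n",
              nrow(x$subjects), sum(x$subjects$group == "control"),
              sum(x$subjects$group == "case"), nrow(x$truth)))
  cat(sprintf("  seed %d; %d volumes clamped at floor\n", x$seed, x$n_clamped))
  invisible(x)
}

#' Default cohort specifications emulating a multi-study lifespan design
#'
#' Controls come from four cohorts with overlapping age windows that
#' together cover ages 1-100; cases come from a single cohort restricted
#' to ages 55-86, matching the older, narrow observation window typical
#' of PSP Richardson-syndrome imaging studies. Pediatric and adult
#' cohorts differ in head size so TIV normalization is exercised.
#'
#' @param n_controls total number of controls, spread over the four
#'   control cohorts (3:6:6:5 weights).
#' @param n_cases number of cases.
#' @return list of [cohort_spec()] objects.
#' @export
psp_cohorts <- function(n_controls = 2000, n_cases = 60) {
  w <- c(3, 6, 6, 5)
  n4 <- pmax(1L, round(n_controls * w / sum(w)))
  list(
    cohort_spec("PED",  "control", n4[1], c(1, 25),   1.30e6, 1.3e5),
    cohort_spec("ADU1", "control", n4[2], c(18, 65),  1.45e6, 1.2e5),
    cohort_spec("ADU2", "control", n4[3], c(35, 90),  1.47e6, 1.2e5),
    cohort_spec("AGE",  "control", n4[4], c(60, 100), 1.44e6, 1.1e5),
    cohort_spec("PSP",  "case",    n_cases, c(55, 86), 1.46e6, 1.2e5))
}

#' Default ground-truth table emulating the PSP-RS atrophy cascade
#'
#' Eleven structures whose onsets and deviation rates reproduce the
#' canonical ordering of atrophy progression in PSP Richardson syndrome:
#' ventral diencephalon first (around age 40, before any case is
#' observable), then pallidum, then brainstem/striatum/amygdala, then a
#' severely affected thalamus, then frontal and finally occipital
#' cortex, plus a spared (non-diverging) hippocampus and cerebellum.
#' Deviation rates are set so the model distances at age 90 are of the
#' magnitude reported for this disease (thalamus ~4 z, pallidum ~2.9,
#' brainstem ~2.4).
#'
#' @param noise_sd observation noise, z-units.
#' @return list of [trajectory_truth()] objects.
#' @export
psp_truths <- function(noise_sd = 0.8) {
  # healthy shapes: rise-and-decline cubic for gray matter, slow linear
  # decline for brainstem-like structures; coefficients keep z within
  # roughly [-2, 1.5] over ages 1-100
  cubic  <- c(-1.8, 0.12, -0.0021, 1e-5)
  quad   <- c(-0.5, 0.06, -7e-4)
  lin    <- c(0.9, -0.018)
  list(
    trajectory_truth("ventral_diencephalon", quad, noise_sd, 40, 0.044,
                     ref_mean = 0.55, ref_sd = 0.05),
    trajectory_truth("pallidum", cubic, noise_sd, 43, 0.062,
                     ref_mean = 0.21, ref_sd = 0.02),
    trajectory_truth("brainstem", lin, noise_sd, 46, 0.055,
                     lr_split = NA, ref_mean = 1.60, ref_sd = 0.12),
    trajectory_truth("putamen", cubic, noise_sd, 46, 0.040,
                     ref_mean = 0.55, ref_sd = 0.05),
    trajectory_truth("caudate", quad, noise_sd, 47, 0.035,
                     ref_mean = 0.50, ref_sd = 0.05),
    trajectory_truth("amygdala", quad, noise_sd, 47, 0.030,
                     ref_mean = 0.12, ref_sd = 0.015),
    trajectory_truth("thalamus", cubic, noise_sd, 50, 0.100,
                     ref_mean = 1.06, ref_sd = 0.09),
    trajectory_truth("supp_motor_cortex", cubic, noise_sd, 53, 0.030,
                     ref_mean = 0.75, ref_sd = 0.07),
    trajectory_truth("occipital_pole", quad, noise_sd, 58, 0.025,
                     ref_mean = 0.45, ref_sd = 0.05),
    trajectory_truth("hippocampus", cubic, noise_sd, NA, 0,
                     ref_mean = 0.55, ref_sd = 0.05),
    trajectory_truth("cerebellum_gm", lin, noise_sd, NA, 0,
                     lr_split = NA, ref_mean = 7.0, ref_sd = 0.55))
}

#' Benchmark scenario for onset-recovery simulations
#'
#' Eight symmetric structures with true onsets 46, 50, ..., 74 years
#' (4 years apart, straddling the start of the case observation window
#' so that pre-window extrapolation is exercised) and a common deviation
#' rate of 0.10 z/yr, observed with 0.8 z noise in 2000 controls (ages
#' 1-100) and 60 cases (ages 55-86) by default.
#'
#' @param n_controls,n_cases cohort sizes.
#' @param noise_sd observation noise, z-units.
#' @param deviation_rate z-units lost per year after onset.
#' @return list with elements `specs` and `truths`, ready for
#'   [simulate_cohort()].
#' @export
recovery_scenario <- function(n_controls = 2000, n_cases = 60,
                              noise_sd = 0.8, deviation_rate = 0.10) {
  onsets <- seq(46, 74, by = 4)
  shapes <- list(c(-0.5, 0.06, -7e-4), c(0.9, -0.018),
                 c(-1.8, 0.12, -0.0021, 1e-5))
  truths <- lapply(seq_along(onsets), function(i) {
    trajectory_truth(sprintf("structure_%02d", i),
                     shapes[[1L + (i - 1L) %% 3L]],
                     noise_sd = noise_sd, onset_age = onsets[i],
                     deviation_rate = deviation_rate,
                     ref_mean = 0.5 + 0.05 * i, ref_sd = 0.05)
  })
  specs <- list(
    cohort_spec("HC",  "control", n_controls, c(1, 100), 1.45e6, 1.2e5),
    cohort_spec("PSP", "case",    n_cases,    c(55, 86), 1.46e6, 1.2e5))
  list(specs = specs, truths = truths)
}
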