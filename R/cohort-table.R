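#' Read a subject volumetric table
#'
#' Reads a CSV (default) or TSV subject table and validates it. Required
#' columns: `subject_id`, `cohort_id`, `group` (control/case), `sex`,
#' `age` (years), `tiv_mm3`; every remaining column is taken to be a raw
#' structure volume in mm3 (`<structure>_L` / `<structure>_R` for
#' hemispheres). Missing `age` or `tiv_mm3` entries are rejected;
#' missing individual structure values are allowed with a warning.
#'
#' @param path file path; `.tsv`/`.txt` are read as tab-separated,
#'   anything else as comma-separated unless `sep` is given.
#' @param sep field separator override.
#' @return validated data.frame.
#' @seealso [write_subject_table()], [validate_subject_table()]
#' @export
read_subject_table <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("input table not found: ", path)
  if (is.null(sep)) {
    sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  }
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                          stringsAsFactors = FALSE, check.names = FALSE,
                          fileEncoding = "UTF-8")
  validate_subject_table(df)
}

#' Write a subject table to CSV at full double precision
#'
#' Numeric columns are rendered with 17 significant digits so that
#' [read_subject_table()] reproduces them bit for bit.
#'
#' @param subjects subject data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_subject_table <- function(subjects, path) {
  utils::write.csv(.format_full_precision(subjects), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Validate a subject table
#'
#' @param df data.frame to check.
#' @return `df`, invisibly classed as before, after validation; errors
#'   name the offending column or subjects.
#' @export
validate_subject_table <- function(df) {
  missing_cols <- setdiff(.subject_cols, names(df))
  if (length(missing_cols)) {
    stop("missing required columns: ", paste(missing_cols, collapse = ", "))
  }
  if (anyNA(df$age) || anyNA(df$tiv_mm3)) {
    stop("missing values in 'age' or 'tiv_mm3' are not allowed")
  }
  if (!is.numeric(df$age) || any(df$age <= 0) || any(df$age > 120)) {
    stop("'age' must be numeric with 0 < age <= 120")
  }
  if (!is.numeric(df$tiv_mm3) || any(df$tiv_mm3 <= 0)) {
    stop("'tiv_mm3' must be positive")
  }
  if (!all(df$group %in% c("control", "case"))) {
    stop("'group' must be 'control' or 'case'")
  }
  struct_cols <- .structure_columns(df)
  if (!length(struct_cols)) stop("no structure volume columns found")
  for (nm in struct_cols) {
    if (!is.numeric(df[[nm]])) stop("structure column not numeric: ", nm)
    if (any(df[[nm]] < 0, na.rm = TRUE)) stop("negative volumes in: ", nm)
  }
  n_na <- sum(is.na(as.matrix(df[struct_cols])))
  if (n_na > 0) {
    warning(sprintf("%d missing structure values present", n_na))
  }
  invisible(df)
}

#' Read a structure-metadata configuration (JSON or YAML)
#'
#' The configuration declares which structures are symmetric (have
#' `_L`/`_R` columns to be summed), which are midline (single column),
#' and the anatomical grouping map used for staging
#' (`groups: {striatum: [putamen, caudate, accumbens], ...}`).
#'
#' @param path `.json`, `.yaml` or `.yml` file.
#' @return list with elements `symmetric`, `midline`, `groups`, and
#'   `grouping_map` (named character vector, structure -> group).
#' @export
read_structure_metadata <- function(path) {
  if (!file.exists(path)) stop("metadata file not found: ", path)
  meta <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  meta$symmetric <- as.character(meta$symmetric %||% character())
  meta$midline <- as.character(meta$midline %||% character())
  groups <- meta$groups %||% list()
  gm <- character()
  for (g in names(groups)) {
    members <- as.character(groups[[g]])
    gm[members] <- g
  }
  meta$grouping_map <- gm
  meta
}

#' Default structure metadata shipped with the package
#'
#' Neuromorphometrics-style declarations for the structures emitted by
#' [psp_truths()], including the striatum and frontal-cortex groupings
#' used when merging divergence events into anatomical stages.
#'
#' @return see [read_structure_metadata()].
#' @export
default_structure_metadata <- function() {
  read_structure_metadata(system.file("extdata", "structure_metadata.json",
                                      package = "brainchart", mustWork = TRUE))
}

#' Sum left and right hemisphere volumes
#'
#' Columns named `<structure>_L` / `<structure>_R` are summed into a
#' single `<structure>` column; columns without a hemisphere suffix
#' (midline structures such as the brainstem or the vermis groups) pass
#' through unchanged. A structure with one hemisphere column but not the
#' other is a hard error naming the structure.
#'
#' @param df subject table (or any data.frame with volume columns).
#' @param symmetric optional character vector of structures that must
#'   have both hemisphere columns; defaults to auto-detection from the
#'   `_L`/`_R` suffixes.
#' @return data.frame with hemisphere pairs replaced by their sums.
#' @export
#' @examples
#' combine_lr(data.frame(thalamus_L = 7000, thalamus_R = 7200,
#'                       brainstem = 22000))
combine_lr <- function(df, symmetric = NULL) {
  nms <- names(df)
  lefts <- sub("_L$", "", nms[grepl("_L$", nms)])
  rights <- sub("_R$", "", nms[grepl("_R$", nms)])
  stems <- union(union(lefts, rights), symmetric %||% character())
  for (s in stems) {
    has_l <- paste0(s, "_L") %in% nms
    has_r <- paste0(s, "_R") %in% nms
    if (!has_l || !has_r) {
      stop("structure '", s, "' is missing its ",
           if (has_l) "right" else "left", " hemisphere column")
    }
  }
  out <- df[, setdiff(nms, c(paste0(stems, "_L"), paste0(stems, "_R"))),
            drop = FALSE]
  for (s in stems) out[[s]] <- df[[paste0(s, "_L")]] + df[[paste0(s, "_R")]]
  out
}

#' Normalize a raw volume to total intracranial volume
#'
#' @param raw raw volume(s), mm3.
#' @param tiv total intracranial volume(s), mm3; must be positive.
#' @return `100 * raw / tiv` — the volume as a percentage of TIV,
#'   invariant to a common rescaling of both arguments.
#' @export
normalize_to_tiv <- function(raw, tiv) {
  if (any(tiv <= 0)) stop("'tiv' must be positive")
  100 * raw / tiv
}

#' Z-score values against a reference sample
#'
#' Standardizes normalized volumes against the control reference so
#' structures of very different sizes share one scale; the reference
#' mean and sd are returned for the inverse transform.
#'
#' @param values numeric values to standardize.
#' @param reference reference sample (>= 2 values, nonzero variance);
#'   defaults to `values` itself.
#' @return list with `z`, `ref_mean`, `ref_sd`.
#' @export
zscore <- function(values, reference = values) {
  reference <- reference[!is.na(reference)]
  if (length(reference) < 2L) stop("reference needs at least 2 values")
  m <- mean(reference)
  s <- stats::sd(reference)
  if (!is.finite(s) || s <= 0) stop("reference variance is zero")
  list(z = (values - m) / s, ref_mean = m, ref_sd = s)
}

#' Per-structure series of z-scored volumes
#'
#' Plain container pairing ages, z-scored normalized volumes and group
#' labels for one structure, together with the reference statistics that
#' produced the z-scores.
#'
#' @param structure structure name.
#' @param ages,values,groups equal-length vectors.
#' @param ref_mean,ref_sd reference statistics (normalized-volume
#'   units); `ref_sd` must be positive.
#' @return object of class `structure_series`.
#' @export
structure_series <- function(structure, ages, values, groups,
                             ref_mean, ref_sd) {
  n <- length(ages)
  if (length(values) != n || length(groups) != n) {
    stop("'ages', 'values' and 'groups' must have equal length")
  }
  if (ref_sd <= 0) stop("'ref_sd' must be > 0")
  structure(list(structure = structure, ages = as.numeric(ages),
                 values = as.numeric(values), groups = as.character(groups),
                 ref_mean = ref_mean, ref_sd = ref_sd),
            class = "structure_series")
}

#' One-sample Kolmogorov-Smirnov normality check
#'
#' Tests whether the (standardized) values are compatible with a normal
#' law, flagging — not excluding — structures that fail at the given
#' level. Fewer than `min_n` usable values, or zero variance, yields
#' status `"untested"`.
#'
#' @param values numeric sample (normalized volumes).
#' @param alpha significance level (default 0.05, i.e. the 95% level).
#' @param min_n minimum usable sample size (default 8).
#' @return list with `statistic`, `p_value`, `reject`, `status`
#'   (`"tested"` or `"untested"`), `n`.
#' @export
ks_normality <- function(values, alpha = 0.05, min_n = 8L) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < min_n || stats::sd(values) == 0 || !is.finite(stats::sd(values))) {
    return(list(statistic = NA_real_, p_value = NA_real_,
                reject = NA, status = "untested", n = n))
  }
  z <- (values - mean(values)) / stats::sd(values)
  kt <- suppressWarnings(stats::ks.test(z, "pnorm"))
  list(statistic = unname(kt$statistic), p_value = kt$p.value,
       reject = kt$p.value < alpha, status = "tested", n = n)
}

#' Combine cases with controls younger than the youngest case
#'
#' Implements the lifespan-constraint rule for the disease model:
#' because neurodegeneration is assumed continuous and progressive, the
#' disease trajectory before the first observable patient is anchored by
#' control subjects strictly younger than the youngest case.
#'
#' @param controls,cases subject data.frames with at least `age` and
#'   `group` columns.
#' @return row-bound data.frame: all cases plus exactly those controls
#'   with `age < min(cases$age)`.
#' @export
#' @examples
#' ctl <- data.frame(age = c(50, 60), group = "control")
#' cas <- data.frame(age = c(55, 70), group = "case")
#' nrow(build_disease_training_set(ctl, cas))  # 3
build_disease_training_set <- function(controls, cases) {
  if (is.null(cases) || nrow(cases) == 0L) {
    stop("at least one case is required")
  }
  youngest <- min(cases$age)
  keep <- controls[controls$age < youngest, , drop = FALSE]
  out <- rbind(keep, cases)
  rownames(out) <- NULL
  out
}

#' Flag subjects lying beyond 2 residual SD of a fitted trajectory
#'
#' Residuals from the fitted curve larger than `threshold` residual
#' standard deviations in absolute value are flagged for review;
#' subjects are never removed automatically.
#'
#' @param ages,values the series the model was fitted on.
#' @param model a [fit_trajectory()] model.
#' @param threshold flagging threshold in residual SD units (default 2).
#' @return logical vector of flags.
#' @export
flag_model_outliers <- function(ages, values, model, threshold = 2) {
  stopifnot(inherits(model, "lifespan_fit"))
  res <- values - predict(model, ages, extrapolate = Inf)
  s <- model$residual_sd
  if (!is.finite(s) || s == 0) return(rep(FALSE, length(res)))
  abs(res) > threshold * s
}
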