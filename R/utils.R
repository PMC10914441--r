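# internal helpers shared across modules

#' Evaluate a polynomial with intercept-first coefficients
#'
#' @param coeffs numeric vector `c(b0, b1, ..., bk)` for
#'   `b0 + b1*x + ... + bk*x^k`.
#' @param x numeric vector of evaluation points.
#' @return numeric vector, same length as `x`.
#' @keywords internal
#' @noRd
eval_poly <- function(coeffs, x) {
  stopifnot(is.numeric(coeffs), length(coeffs) >= 1L)
  drop(outer(as.numeric(x), seq_along(coeffs) - 1L, `^`) %*% coeffs)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# demographic columns of a subject table, in canonical order
.subject_cols <- c("subject_id", "cohort_id", "group", "sex", "age", "tiv_mm3")

.structure_columns <- function(df) setdiff(names(df), .subject_cols)

# numeric columns rendered at full double precision so that a written
# table reads back bit-identical
.format_full_precision <- function(df) {
  for (nm in names(df)) {
    if (is.numeric(df[[nm]]) && !is.integer(df[[nm]])) {
      df[[nm]] <- sprintf("%.17g", df[[nm]])
    }
  }
  df
}
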