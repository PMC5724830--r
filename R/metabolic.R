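# HOMA-IR --------------------------------------------------------------------

#' Homeostatic model assessment of insulin resistance (HOMA-IR)
#'
#' Matthews' surrogate index of insulin resistance from fasting plasma
#' measurements.  In mass units, `HOMA-IR = glucose [mg/dl] x insulin
#' [uU/ml] / 405`; with glucose in SI units the divisor is 22.5
#' (`glucose [mmol/l] x insulin / 22.5`), and the two agree because
#' 405 / 22.5 = 18, the molar-mass conversion for glucose.  The constant is
#' calibrated so that a normal fasting pair (glucose 90 mg/dl = 5 mmol/l,
#' insulin 4.5 uU/ml) scores 1.0.
#'
#' @param glucose Fasting plasma glucose, in `glucose_units`.  Must be
#'   positive.
#' @param insulin Fasting plasma insulin in uU/ml (non-negative).
#' @param glucose_units `"mg/dl"` (default) or `"mmol/l"`.
#' @return Dimensionless HOMA-IR score(s); vectorized and linear in each
#'   argument.
#' @examples
#' homa_ir(133, 24.2)        # ~7.95
#' homa_ir(90, 4.5)          # 1.0
#' homa_ir(5, 4.5, "mmol/l") # 1.0
#' @export
homa_ir <- function(glucose, insulin, glucose_units = c("mg/dl", "mmol/l")) {
  glucose_units <- match.arg(glucose_units)
  if (!is.numeric(glucose) || !is.numeric(insulin))
    stop_validation("glucose and insulin must be numeric")
  if (any(!is.na(glucose) & glucose <= 0))
    stop_validation("glucose must be positive")
  if (any(!is.na(insulin) & insulin < 0))
    stop_validation("insulin must be non-negative")
  divisor <- if (glucose_units == "mg/dl") 405 else 22.5
  glucose * insulin / divisor
}

#' Append a HOMA-IR column to a cohort table
#'
#' @param cohort Cohort data frame.
#' @param glucose_col,insulin_col Column names holding fasting glucose and
#'   insulin.
#' @param glucose_units Passed to [homa_ir()].
#' @return The cohort with an added `homa_ir` column.
#' @export
add_homa_ir <- function(cohort, glucose_col = "glucose_mgdl",
                        insulin_col = "insulin_uUml",
                        glucose_units = c("mg/dl", "mmol/l")) {
  chk_cols(cohort, c(glucose_col, insulin_col), "cohort table")
  cohort$homa_ir <- homa_ir(cohort[[glucose_col]], cohort[[insulin_col]],
                            glucose_units = glucose_units)
  cohort
}
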