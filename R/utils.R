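# Small shared helpers: input checking, date arithmetic, rounding.

`%||%` <- rlang::`%||%`

#' Round half up
#'
#' Decimal rounding where ties go away from zero (`0.05 -> 0.1`), the
#' convention used when reporting percentages to one decimal. Base
#' `round()` rounds half to even, which would turn 50.95 into 50.9.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Numeric vector of the same length.
#' @export
#' @examples
#' round_half_up(c(50.95, 50.94, -1.25), 1)
round_half_up <- function(x, digits = 1) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

# stop with a consistent error class so callers can condition on it
abort_input <- function(msg, field = NULL) {
  abort(msg, class = "ckdvalid_input_error", field = field)
}

check_choice <- function(x, choices, field) {
  bad <- setdiff(unique(as.character(x)), choices)
  if (length(bad) > 0) {
    abort_input(
      sprintf(
        "Invalid value(s) for `%s`: %s. Must be one of: %s.",
        field, paste(sQuote(bad), collapse = ", "),
        paste(choices, collapse = ", ")
      ),
      field = field
    )
  }
  invisible(x)
}

check_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort_input(sprintf(
      "%s is missing required column(s): %s.",
      what, paste(missing, collapse = ", ")
    ))
  }
  invisible(df)
}

as_date_strict <- function(x, field) {
  if (inherits(x, "Date")) return(x)
  out <- as.Date(as.character(x), format = "%Y-%m-%d")
  if (anyNA(out) && !all(is.na(x) == is.na(out))) {
    abort_input(
      sprintf("`%s` contains values that do not parse as ISO-8601 dates.", field),
      field = field
    )
  }
  out
}

# Age in exact fractional years; used inside the eGFR equation so that
# trajectories have no birthday step artifacts.
age_fractional <- function(birth_date, at_date) {
  as.numeric(at_date - birth_date) / 365.25
}

# Completed age in whole calendar years (birthday arithmetic), used for
# eligibility and age-class assignment.
age_completed <- function(birth_date, at_date) {
  floor(lubridate::time_length(lubridate::interval(birth_date, at_date), "years"))
}

#' Age classes used for stratified validation
#'
#' @param age Completed age in years (numeric vector).
#' @return Factor with levels `19-44`, `45-64`, `65-74`, `75-84`, `85+`;
#'   ages below 19 give `NA`.
#' @export
age_class_of <- function(age) {
  cut(age,
    breaks = c(19, 45, 65, 75, 85, Inf), right = FALSE,
    labels = c("19-44", "45-64", "65-74", "75-84", "85+")
  )
}
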