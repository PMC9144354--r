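# eGFR engine: 2021 race-free CKD-EPI creatinine equation, G-stage bands,
# and the analytic inverse used by the synthetic-data generator.

#' CKD-EPI 2021 (race-free) equation constants
#'
#' The published coefficient set of the 2021 creatinine-only CKD-EPI
#' equation without a race term:
#' \deqn{eGFR = 142 \times \min(Scr/\kappa, 1)^{\alpha} \times
#'   \max(Scr/\kappa, 1)^{-1.200} \times 0.9938^{age}
#'   \times 1.012\,[\mathrm{if\ female}]}
#' with \eqn{\kappa} = 0.7 (female) / 0.9 (male) mg/dL and
#' \eqn{\alpha} = -0.241 (female) / -0.302 (male).
#'
#' One frozen constant set per equation name; only `"ckd_epi_2021"` is
#' implemented (MDRD and cystatin variants are deliberately out of scope).
#'
#' @param equation Equation name; only `"ckd_epi_2021"`.
#' @return Named list of constants.
#' @export
#' @examples
#' ckd_epi_constants()$scale
ckd_epi_constants <- function(equation = "ckd_epi_2021") {
  check_choice(equation, "ckd_epi_2021", "equation")
  list(
    equation = "ckd_epi_2021",
    kappa_female = 0.7,
    kappa_male = 0.9,
    alpha_female = -0.241,
    alpha_male = -0.302,
    max_exponent = -1.200,
    age_base = 0.9938,
    female_multiplier = 1.012,
    scale = 142
  )
}

#' Estimated glomerular filtration rate (CKD-EPI 2021, race-free)
#'
#' Computes eGFR in mL/min/1.73 m\eqn{^2} from serum creatinine, age and
#' sex using the 2021 race-free CKD-EPI creatinine equation. No rounding
#' is applied; staging thresholds compare the full floating-point value.
#'
#' @param scr Serum creatinine in mg/dL (strictly positive). Values in
#'   other units (e.g. \eqn{\mu}mol/L) are rejected implicitly by range
#'   checks elsewhere, never converted silently.
#' @param age Age in years at the measurement date, may be fractional;
#'   must lie in (0, 120).
#' @param sex `"male"` or `"female"` (recycled against `scr`).
#' @param equation Equation name; only `"ckd_epi_2021"`.
#' @return Numeric vector of eGFR values, mL/min/1.73 m\eqn{^2}.
#' @seealso [stage_from_egfr()], [creatinine_from_egfr()]
#' @export
#' @examples
#' egfr_ckd_epi(1.0, age = 50, sex = "male")
#' egfr_ckd_epi(c(0.7, 1.4), age = 60, sex = "female")
egfr_ckd_epi <- function(scr, age, sex, equation = "ckd_epi_2021") {
  k <- ckd_epi_constants(equation)
  if (!is.numeric(scr) || anyNA(scr) || any(scr <= 0)) {
    abort_input("`scr` must be positive serum creatinine in mg/dL.", field = "scr")
  }
  if (!is.numeric(age) || anyNA(age) || any(age <= 0) || any(age >= 120)) {
    abort_input("`age` must lie strictly between 0 and 120 years.", field = "age")
  }
  check_choice(sex, c("male", "female"), "sex")
  n <- max(length(scr), length(age), length(sex))
  scr <- rep_len(scr, n)
  age <- rep_len(age, n)
  sex <- rep_len(as.character(sex), n)

  female <- sex == "female"
  kappa <- ifelse(female, k$kappa_female, k$kappa_male)
  alpha <- ifelse(female, k$alpha_female, k$alpha_male)
  r <- scr / kappa
  k$scale * pmin(r, 1)^alpha * pmax(r, 1)^k$max_exponent *
    k$age_base^age * ifelse(female, k$female_multiplier, 1)
}

stage_levels <- function() c("GE60", "S45_59", "S30_44", "S15_29", "LT15")

#' eGFR stage bands
#'
#' Maps eGFR to the G-stage bands used for CKD-range grading. Bands are
#' half-open, closed at the lower edge, so 60.0 falls in `GE60`
#' (eGFR \eqn{\ge} 60 is non-CKD-range) and 29.999 in `S15_29`.
#'
#' @param egfr Positive eGFR values, mL/min/1.73 m\eqn{^2}.
#' @return Factor with levels `GE60` (\eqn{\ge}60), `S45_59` ([45,60)),
#'   `S30_44` ([30,45)), `S15_29` ([15,30)), `LT15` ((0,15)).
#' @export
#' @examples
#' stage_from_egfr(c(95, 60, 59.9, 14.2))
stage_from_egfr <- function(egfr) {
  if (!is.numeric(egfr) || anyNA(egfr) || any(egfr <= 0)) {
    abort_input("`egfr` must be strictly positive.", field = "egfr")
  }
  out <- cut(egfr,
    breaks = c(0, 15, 30, 45, 60, Inf), right = FALSE,
    labels = c("LT15", "S15_29", "S30_44", "S45_59", "GE60")
  )
  factor(as.character(out), levels = stage_levels())
}

#' Invert the CKD-EPI 2021 equation
#'
#' Returns the unique serum creatinine that yields a target eGFR for a
#' given age and sex. The equation is strictly decreasing in creatinine,
#' so the inverse is closed-form: on the low-creatinine branch
#' (`scr < kappa`) the exponent is the sex-specific \eqn{\alpha}, on the
#' high branch it is -1.200. Used by the synthetic-data generator to
#' convert latent eGFR trajectories into creatinine measurements.
#'
#' @param egfr Target eGFR, mL/min/1.73 m\eqn{^2}.
#' @param age,sex As in [egfr_ckd_epi()].
#' @param equation Equation name.
#' @return Serum creatinine in mg/dL such that
#'   `egfr_ckd_epi(scr, age, sex)` reproduces `egfr` to within 1e-9.
#'   Targets requiring creatinine outside the physiological range
#'   (0.05, 25) mg/dL raise an unattainable-value error.
#' @export
#' @examples
#' creatinine_from_egfr(60, age = 70, sex = "female")
creatinine_from_egfr <- function(egfr, age, sex, equation = "ckd_epi_2021") {
  k <- ckd_epi_constants(equation)
  if (!is.numeric(egfr) || anyNA(egfr) || any(egfr <= 0)) {
    abort_input("`egfr` must be strictly positive.", field = "egfr")
  }
  check_choice(sex, c("male", "female"), "sex")
  n <- max(length(egfr), length(age), length(sex))
  egfr <- rep_len(egfr, n)
  age <- rep_len(age, n)
  sex <- rep_len(as.character(sex), n)

  female <- sex == "female"
  kappa <- ifelse(female, k$kappa_female, k$kappa_male)
  alpha <- ifelse(female, k$alpha_female, k$alpha_male)
  base <- k$scale * k$age_base^age * ifelse(female, k$female_multiplier, 1)
  ratio <- egfr / base
  # ratio <= 1 <=> scr >= kappa (high-creatinine branch)
  scr <- kappa * ifelse(ratio <= 1, ratio^(1 / k$max_exponent), ratio^(1 / alpha))
  bad <- scr < 0.05 | scr > 25
  if (any(bad)) {
    abort(
      sprintf(
        "%d eGFR target(s) are unattainable: implied creatinine outside (0.05, 25) mg/dL.",
        sum(bad)
      ),
      class = "ckdvalid_unattainable_error"
    )
  }
  scr
}

#' Append eGFR and stage to creatinine records
#'
#' Joins subject demographics onto a table of dated serum creatinine
#' measurements and appends `egfr` and `stage` columns. Age enters the
#' equation in exact fractional years at each measurement date.
#'
#' @param creatinine Data frame with columns `subject_id`, `date`,
#'   `scr_mg_dl`, `setting` (one of inpatient / outpatient / emergency).
#' @param subjects Data frame with columns `subject_id`, `sex`,
#'   `birth_date`.
#' @param equation Equation name passed to [egfr_ckd_epi()].
#' @return A tibble: the input records plus `egfr` and `stage`.
#' @export
#' @examples
#' subjects <- tibble::tibble(
#'   subject_id = "s1", sex = "female", birth_date = as.Date("1950-06-01")
#' )
#' scr <- tibble::tibble(
#'   subject_id = "s1", date = as.Date("2013-03-01"),
#'   scr_mg_dl = 1.1, setting = "outpatient"
#' )
#' add_egfr(scr, subjects)
add_egfr <- function(creatinine, subjects, equation = "ckd_epi_2021") {
  check_columns(creatinine, c("subject_id", "date", "scr_mg_dl", "setting"), "`creatinine`")
  check_columns(subjects, c("subject_id", "sex", "birth_date"), "`subjects`")
  check_choice(creatinine$setting, c("inpatient", "outpatient", "emergency"), "setting")
  orphans <- setdiff(creatinine$subject_id, subjects$subject_id)
  if (length(orphans) > 0) {
    abort(
      sprintf(
        "Creatinine records reference %d subject id(s) absent from `subjects`: %s.",
        length(orphans), paste(head(orphans, 5), collapse = ", ")
      ),
      class = "ckdvalid_linkage_error"
    )
  }
  out <- creatinine %>%
    as_tibble() %>%
    mutate(date = as_date_strict(.data$date, "date")) %>%
    left_join(
      subjects %>%
        select("subject_id", "sex", "birth_date") %>%
        mutate(birth_date = as_date_strict(.data$birth_date, "birth_date")),
      by = "subject_id"
    )
  if (any(out$birth_date >= out$date)) {
    abort_input("Every measurement must postdate the subject's birth date.", field = "date")
  }
  out %>%
    mutate(
      egfr = egfr_ckd_epi(
        .data$scr_mg_dl,
        age_fractional(.data$birth_date, .data$date),
        .data$sex,
        equation = equation
      ),
      stage = stage_from_egfr(.data$egfr)
    ) %>%
    select(-"sex", -"birth_date")
}
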