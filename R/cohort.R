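# Cohort building: eligibility, index-date selection and the longitudinal
# working-standard CKD label derived from each subject's eGFR series.

#' Study window and pipeline thresholds
#'
#' Container for the accrual window, linkage lookback/lookahead and the
#' chronicity gap. Defaults mirror a regional validation design: creatinine
#' accrual 2012-01-01 to 2015-01-31, residency and administrative linkage
#' over 5 years before to 1 year after the index date, and a 90-day
#' chronicity gap standing in for "at least 3 months" (calendar-month
#' arithmetic is ambiguous at month ends, so the gap is expressed in days
#' and is configurable).
#'
#' @param start,end Accrual window bounds (coerced to `Date`).
#' @param lookback_years,lookahead_years Administrative/residency window
#'   around the index date, in whole years.
#' @param chronicity_gap_days Minimum separation, in days, between the
#'   two measurements establishing chronicity.
#' @return An object of class `study_window`.
#' @export
#' @examples
#' study_window()
study_window <- function(start = "2012-01-01", end = "2015-01-31",
                         lookback_years = 5, lookahead_years = 1,
                         chronicity_gap_days = 90) {
  start <- as_date_strict(start, "start")
  end <- as_date_strict(end, "end")
  if (start >= end) abort_input("`start` must precede `end`.", field = "start")
  if (lookback_years <= 0 || lookahead_years <= 0 || chronicity_gap_days <= 0) {
    abort_input("Window durations must be positive.")
  }
  structure(
    list(
      start = start, end = end,
      lookback_years = lookback_years, lookahead_years = lookahead_years,
      chronicity_gap_days = chronicity_gap_days
    ),
    class = "study_window"
  )
}

#' @export
print.study_window <- function(x, ...) {
  cat(sprintf(
    "<study_window> %s to %s | lookback %dy, lookahead %dy, chronicity gap %dd\n",
    format(x$start), format(x$end),
    x$lookback_years, x$lookahead_years, x$chronicity_gap_days
  ))
  invisible(x)
}

window_lookback_start <- function(index_date, window) {
  index_date %m-% lubridate::years(window$lookback_years)
}

window_lookahead_end <- function(index_date, window) {
  index_date %m+% lubridate::years(window$lookahead_years)
}

#' @importFrom lubridate %m-% %m+%
NULL

#' Select the index date from a measurement series
#'
#' The index date anchoring all windows is the date of the subject's
#' chronologically last creatinine measurement inside the accrual window.
#'
#' @param dates Measurement dates (`Date` vector).
#' @param window A [study_window()].
#' @return The index `Date`.
#'   Signals a condition of class `ckdvalid_not_eligible` when no
#'   measurement falls inside the window.
#' @export
select_index_date <- function(dates, window = study_window()) {
  dates <- as_date_strict(dates, "dates")
  in_win <- dates[dates >= window$start & dates <= window$end]
  if (length(in_win) == 0) {
    abort("No measurement inside the accrual window.", class = "ckdvalid_not_eligible")
  }
  max(in_win)
}

# ---- residency intervals ----------------------------------------------------

#' Parse and serialize residency intervals
#'
#' Residency is stored as semicolon-separated ISO-8601 date pairs, e.g.
#' `"2000-01-01/2013-06-30;2013-06-30/2020-12-31"`. Intervals must be
#' chronologically ordered and non-overlapping; abutting intervals (the
#' end of one equals the start of the next) count as continuous coverage.
#'
#' @param x A single serialized residency string.
#' @return `parse_residency()`: a tibble with `start` and `end` Date
#'   columns; `format_residency()` is its inverse.
#' @export
parse_residency <- function(x) {
  if (is.na(x) || !nzchar(x)) {
    return(tibble(start = as.Date(character()), end = as.Date(character())))
  }
  pairs <- strsplit(strsplit(x, ";", fixed = TRUE)[[1]], "/", fixed = TRUE)
  if (any(lengths(pairs) != 2)) {
    abort_input("Residency intervals must be 'start/end' date pairs separated by ';'.",
      field = "residency"
    )
  }
  out <- tibble(
    start = as_date_strict(vapply(pairs, `[`, "", 1), "residency"),
    end = as_date_strict(vapply(pairs, `[`, "", 2), "residency")
  )
  if (any(out$start > out$end)) {
    abort_input("Residency interval start dates must not exceed end dates.",
      field = "residency"
    )
  }
  if (nrow(out) > 1 && any(out$start[-1] < out$end[-nrow(out)])) {
    abort_input("Residency intervals must be ordered and non-overlapping.",
      field = "residency"
    )
  }
  out
}

#' @rdname parse_residency
#' @param intervals A tibble with `start`/`end` Date columns.
#' @export
format_residency <- function(intervals) {
  paste(sprintf("%s/%s", format(intervals$start), format(intervals$end)),
    collapse = ";"
  )
}

# Vectorized parse of many serialized residency strings into one long
# table (numeric dates); the per-subject coverage check in build_cohort
# runs off this rather than calling parse_residency() 30k times.
parse_residency_long <- function(subject_id, residency) {
  parts <- strsplit(residency, ";", fixed = TRUE)
  flat <- unlist(parts)
  tibble(
    subject_id = rep(subject_id, lengths(parts)),
    start = as.numeric(as.Date(sub("/.*", "", flat))),
    end = as.numeric(as.Date(sub(".*/", "", flat)))
  )
}

# residency coverage of [from, to] for many subjects at once; `need` has
# subject_id, from, to (numeric dates). Returns need + covered flag.
residency_covers_all <- function(subject_id, residency, need) {
  res <- parse_residency_long(subject_id, residency) %>%
    inner_join(need, by = "subject_id")
  # merge overlapping/abutting intervals, then test any merged segment
  merged <- res %>%
    arrange(.data$subject_id, .data$start) %>%
    group_by(.data$subject_id) %>%
    mutate(
      prev_end = dplyr::lag(cummax(.data$end)),
      seg = cumsum(is.na(.data$prev_end) | .data$start > .data$prev_end)
    ) %>%
    group_by(.data$subject_id, .data$seg) %>%
    summarise(
      seg_start = min(.data$start), seg_end = max(.data$end),
      covered = .data$seg_start <= .data$from[1] & .data$seg_end >= .data$to[1],
      .groups = "drop"
    ) %>%
    group_by(.data$subject_id) %>%
    summarise(covered = any(.data$covered), .groups = "drop")
  need %>%
    left_join(merged, by = "subject_id") %>%
    mutate(covered = dplyr::coalesce(.data$covered, FALSE))
}

# TRUE when the (merged, abutment-tolerant) intervals cover [from, to]
residency_covers <- function(intervals, from, to) {
  if (nrow(intervals) == 0) return(FALSE)
  cur_start <- intervals$start[1]
  cur_end <- intervals$end[1]
  for (i in seq_len(nrow(intervals))[-1]) {
    if (intervals$start[i] <= cur_end) {
      cur_end <- max(cur_end, intervals$end[i])
    } else {
      if (cur_start <= from && cur_end >= to) return(TRUE)
      cur_start <- intervals$start[i]
      cur_end <- intervals$end[i]
    }
  }
  cur_start <= from && cur_end >= to
}

# ---- eligibility ------------------------------------------------------------

#' Eligibility of a single subject
#'
#' A subject enters the cohort when (a) at least two in-window
#' measurements exist with some pair separated by at least the chronicity
#' gap, (b) completed age at the index date is at least 19 years, and
#' (c) residency intervals cover the full lookback-to-lookahead span
#' around the index date.
#'
#' @param subject A list or one-row data frame with `birth_date` and
#'   `residency` (serialized intervals, see [parse_residency()]).
#' @param measurements Data frame with a `date` column (the subject's
#'   eGFR records).
#' @param window A [study_window()].
#' @return A list with `eligible` (logical) and `reasons` (character
#'   vector of failing criterion codes among `"gap"`, `"age"`,
#'   `"residency"`; empty when eligible). Ineligibility is a result, not
#'   an error.
#' @export
is_eligible <- function(subject, measurements, window = study_window()) {
  dates <- as_date_strict(measurements$date, "date")
  dates <- dates[dates >= window$start & dates <= window$end]
  reasons <- character()
  if (length(dates) < 2 ||
    as.numeric(max(dates) - min(dates)) < window$chronicity_gap_days) {
    reasons <- c(reasons, "gap")
  }
  if (length(dates) > 0) {
    index_date <- max(dates)
    birth <- as_date_strict(subject$birth_date, "birth_date")
    if (age_completed(birth, index_date) < 19) reasons <- c(reasons, "age")
    res <- parse_residency(subject$residency)
    if (!residency_covers(
      res,
      window_lookback_start(index_date, window),
      window_lookahead_end(index_date, window)
    )) {
      reasons <- c(reasons, "residency")
    }
  }
  list(eligible = length(reasons) == 0, reasons = reasons)
}

# ---- working standard -------------------------------------------------------

ckd_label_levels <- function() c("NO_CKD", "CKD", "ADVANCED_CKD")

# index eGFR under the same-day duplicate rule: keep the highest eGFR
# (lowest creatinine) among measurements on the index date
index_egfr_of <- function(dates, egfr, index_date) {
  max(egfr[dates == index_date])
}

#' Working-standard CKD label from an eGFR series
#'
#' The laboratory working standard labels a subject from repeated eGFR
#' values: let L be the eGFR at the index date (same-day duplicates
#' resolved to the highest eGFR). If L < 30 and some measurement with
#' eGFR < 60 is dated at least `gap_days` before the index date, the
#' label is `ADVANCED_CKD`; if L < 60 with such an earlier measurement,
#' `CKD`; otherwise `NO_CKD`. Only measurements strictly before the
#' index date can establish chronicity — the index measurement is the
#' most recent by construction.
#'
#' @param measurements Data frame with `date` and `egfr` columns.
#' @param index_date The subject's index date (see [select_index_date()]).
#' @param gap_days Chronicity gap in days (default 90).
#' @return One of `"NO_CKD"`, `"CKD"`, `"ADVANCED_CKD"` (factor).
#' @export
#' @examples
#' m <- tibble::tibble(
#'   date = as.Date("2013-01-01") + c(0, 120),
#'   egfr = c(55, 25)
#' )
#' working_standard_label(m, as.Date("2013-05-01"), 90)
working_standard_label <- function(measurements, index_date, gap_days = 90) {
  check_columns(measurements, c("date", "egfr"), "`measurements`")
  dates <- as_date_strict(measurements$date, "date")
  index_date <- as_date_strict(index_date, "index_date")
  if (!any(dates == index_date)) {
    abort("No measurement on the index date; was the index date selected from this series?",
      class = "ckdvalid_internal_error"
    )
  }
  L <- index_egfr_of(dates, measurements$egfr, index_date)
  chronic <- any(measurements$egfr < 60 &
    as.numeric(index_date - dates) >= gap_days)
  value <- if (L < 30 && chronic) {
    "ADVANCED_CKD"
  } else if (L < 60 && chronic) {
    "CKD"
  } else {
    "NO_CKD"
  }
  factor(value, levels = ckd_label_levels())
}

#' Restrict a measurement series to the outpatient setting
#'
#' Used by the outpatient sensitivity analysis: eligibility, index dates
#' and working-standard labels are recomputed downstream on the filtered
#' series.
#'
#' @param measurements Data frame with a `setting` column.
#' @return The records with `setting == "outpatient"`.
#' @export
restrict_outpatient <- function(measurements) {
  check_columns(measurements, "setting", "`measurements`")
  filter(measurements, .data$setting == "outpatient")
}

# ---- cohort assembly --------------------------------------------------------

#' Build the study cohort
#'
#' Applies eligibility, selects index dates and assigns working-standard
#' labels for every subject, in one pass over the eGFR records.
#'
#' @param subjects Tibble with `subject_id`, `sex`, `birth_date`,
#'   `residency` (serialized intervals).
#' @param egfr_records Tibble of measurements with `subject_id`, `date`,
#'   `egfr` (as produced by [add_egfr()]).
#' @param window A [study_window()].
#' @return A tibble with one row per subject: `subject_id`, `sex`,
#'   `n_measurements`, `index_date`, `age_at_index`, `age_class`,
#'   `eligible`, `reasons` (comma-joined failing criteria, `""` when
#'   eligible) and `ws_label` (`NA` for ineligible subjects).
#' @export
build_cohort <- function(subjects, egfr_records, window = study_window()) {
  check_columns(subjects, c("subject_id", "sex", "birth_date", "residency"), "`subjects`")
  check_columns(egfr_records, c("subject_id", "date", "egfr"), "`egfr_records`")
  gap <- window$chronicity_gap_days

  meas <- egfr_records %>%
    as_tibble() %>%
    mutate(date_num = as.numeric(as_date_strict(.data$date, "date"))) %>%
    filter(
      .data$date_num >= as.numeric(window$start),
      .data$date_num <= as.numeric(window$end)
    )

  per_subject <- meas %>%
    group_by(.data$subject_id) %>%
    summarise(
      n_measurements = n(),
      index_num = max(.data$date_num),
      index_egfr = max(.data$egfr[.data$date_num == max(.data$date_num)]),
      span_ok = max(.data$date_num) - min(.data$date_num) >= gap,
      chronic = any(.data$egfr < 60 &
        max(.data$date_num) - .data$date_num >= gap),
      .groups = "drop"
    )

  out <- subjects %>%
    as_tibble() %>%
    mutate(birth_date = as_date_strict(.data$birth_date, "birth_date")) %>%
    left_join(per_subject, by = "subject_id") %>%
    mutate(
      n_measurements = dplyr::coalesce(.data$n_measurements, 0L),
      index_date = as.Date(.data$index_num, origin = "1970-01-01"),
      age_at_index = if_else(
        is.na(.data$index_date), NA_real_,
        as.numeric(age_completed(.data$birth_date, .data$index_date))
      ),
      age_class = age_class_of(.data$age_at_index),
      gap_ok = .data$n_measurements >= 2 & dplyr::coalesce(.data$span_ok, FALSE)
    )

  with_index <- !is.na(out$index_date)
  need <- tibble(
    subject_id = out$subject_id[with_index],
    from = as.numeric(window_lookback_start(out$index_date[with_index], window)),
    to = as.numeric(window_lookahead_end(out$index_date[with_index], window))
  )
  coverage <- residency_covers_all(
    out$subject_id[with_index], out$residency[with_index], need
  )
  out <- out %>%
    left_join(select(coverage, "subject_id", "covered"), by = "subject_id") %>%
    mutate(
      age_ok = !is.na(.data$age_at_index) & .data$age_at_index >= 19,
      res_ok = dplyr::coalesce(.data$covered, FALSE),
      eligible = .data$gap_ok & .data$age_ok & .data$res_ok,
      reasons = paste0(
        if_else(.data$gap_ok, "", "gap,"),
        if_else(.data$age_ok | is.na(.data$index_date), "", "age,"),
        if_else(.data$res_ok | is.na(.data$index_date), "", "residency,")
      ),
      reasons = sub(",$", "", .data$reasons),
      ws_label = factor(
        case_when(
          !.data$eligible ~ NA_character_,
          .data$index_egfr < 30 & .data$chronic ~ "ADVANCED_CKD",
          .data$index_egfr < 60 & .data$chronic ~ "CKD",
          TRUE ~ "NO_CKD"
        ),
        levels = ckd_label_levels()
      )
    ) %>%
    select(
      "subject_id", "sex", "n_measurements", "index_date",
      "age_at_index", "age_class", "eligible", "reasons", "ws_label"
    )
  out
}

# ---- readers / writers ------------------------------------------------------

#' Read and write the subjects table
#'
#' CSV schema: `subject_id`, `sex` (male/female), `birth_date`
#' (ISO-8601), `residency` (semicolon-separated `start/end` date pairs).
#'
#' @param path File path.
#' @return A tibble of subjects.
#' @export
read_subjects_csv <- function(path) {
  df <- readr::read_csv(path,
    col_types = readr::cols(
      subject_id = readr::col_character(),
      sex = readr::col_character(),
      birth_date = readr::col_date(),
      residency = readr::col_character()
    )
  )
  check_columns(df, c("subject_id", "sex", "birth_date", "residency"), path)
  check_choice(df$sex, c("male", "female"), "sex")
  if (anyDuplicated(df$subject_id)) {
    abort_input("Duplicate subject ids in subjects file.", field = "subject_id")
  }
  df
}

#' @rdname read_subjects_csv
#' @param subjects Tibble as returned by [read_subjects_csv()].
#' @export
write_subjects_csv <- function(subjects, path) {
  readr::write_csv(subjects, path)
  invisible(path)
}

#' Read and write creatinine records
#'
#' CSV schema: `subject_id`, `date` (ISO-8601), `scr_mg_dl` (serum
#' creatinine, mg/dL only — other units are rejected upstream, never
#' converted), `setting` (inpatient/outpatient/emergency). The writer
#' appends `egfr` and `stage` columns when present.
#'
#' @param path File path.
#' @return A tibble of creatinine records.
#' @export
read_creatinine_csv <- function(path) {
  df <- readr::read_csv(path,
    col_types = readr::cols(
      subject_id = readr::col_character(),
      date = readr::col_date(),
      scr_mg_dl = readr::col_double(),
      setting = readr::col_character()
    )
  )
  check_columns(df, c("subject_id", "date", "scr_mg_dl", "setting"), path)
  check_choice(df$setting, c("inpatient", "outpatient", "emergency"), "setting")
  if (any(df$scr_mg_dl <= 0)) {
    abort_input("`scr_mg_dl` must be strictly positive.", field = "scr_mg_dl")
  }
  df
}

#' @rdname read_creatinine_csv
#' @param records Tibble of creatinine records (optionally with `egfr`,
#'   `stage`).
#' @export
write_creatinine_csv <- function(records, path) {
  readr::write_csv(records, path)
  invisible(path)
}

#' Write the cohort table
#'
#' @param cohort Tibble as returned by [build_cohort()].
#' @param path File path.
#' @export
write_cohort_csv <- function(cohort, path) {
  readr::write_csv(cohort, path)
  invisible(path)
}
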