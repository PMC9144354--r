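# Administrative-data CKD classifier: a rule engine over coded events
# from the four linked health-information systems, evaluated in a 6-year
# window around each subject's index date (5 years before, 1 after).

#' Filter events to the administrative linkage window
#'
#' Keeps events dated inside the closed interval
#' `[index - lookback, index + lookahead]` (both boundaries included;
#' boundary convention configurable only by changing the window
#' durations). Order-preserving.
#'
#' @param events Tibble with at least a `date` column; if `index_date`
#'   is a data frame, also `subject_id`.
#' @param index_date Either a single `Date` applied to all events, or a
#'   data frame `subject_id`/`index_date` joined per subject.
#' @param window A [study_window()].
#' @return The in-window events.
#' @export
events_in_window <- function(events, index_date, window = study_window()) {
  events <- as_tibble(events)
  if (nrow(events) == 0) return(events)
  events <- mutate(events, date = as_date_strict(.data$date, "date"))
  if (is.data.frame(index_date)) {
    check_columns(index_date, c("subject_id", "index_date"), "`index_date`")
    events <- events %>%
      inner_join(select(index_date, "subject_id", "index_date"), by = "subject_id") %>%
      filter(
        .data$date >= window_lookback_start(.data$index_date, window),
        .data$date <= window_lookahead_end(.data$index_date, window)
      ) %>%
      select(-"index_date")
  } else {
    idx <- as_date_strict(index_date, "index_date")
    events <- filter(
      events,
      .data$date >= window_lookback_start(idx, window),
      .data$date <= window_lookahead_end(idx, window)
    )
  }
  events
}

check_event_sources <- function(events) {
  check_columns(events, c("date", "source", "code"), "`events`")
  check_choice(events$source, admin_sources(), "source")
  if (any(!nzchar(as.character(events$code)))) {
    abort_input("Event codes must be non-empty.", field = "code")
  }
  invisible(events)
}

# per-event criterion flags; shared by the single-subject and the
# vectorized classifiers
event_flags <- function(events, config) {
  src <- as.character(events$source)
  ckd_hit <- rep(FALSE, nrow(events))
  for (s in names(config$ckd_codes)) {
    sel <- src == s
    if (any(sel)) {
      ckd_hit[sel] <- match_prefix(events$code[sel], config$ckd_codes[[s]])
    }
  }
  tibble(
    ckd_hit = ckd_hit,
    dialysis = match_prefix(events$code, config$dialysis_codes),
    transplant = match_prefix(events$code, config$transplant_codes),
    adv_discharge = src == "hospital_discharge" &
      match_prefix(events$code, config$advanced_discharge_codes),
    adv_drug = src == "drug_dispensing" &
      match_prefix(events$code, config$advanced_drug_codes)
  )
}

chronic_dialysis <- function(dates, config) {
  length(dates) >= config$chronic_dialysis_min_events &&
    as.numeric(max(dates) - min(dates)) >= config$chronic_dialysis_min_span_days
}

#' Classify a single subject's events
#'
#' `classify_advanced()` fires on any of the four severity criteria:
#' chronic dialysis (at least `chronic_dialysis_min_events`
#' dialysis-coded events spanning at least
#' `chronic_dialysis_min_span_days`), at least one kidney transplant,
#' one hospital discharge carrying a G4+ diagnosis code, or one
#' dispensing of a listed drug. `classify_ckd()` fires on any per-source
#' CKD code hit, or whenever the advanced criteria fire (advanced
#' implies CKD). Events are assumed already window-filtered.
#'
#' @param events One subject's events: `date`, `source`, `code`.
#' @param config A [default_code_config()]-style `ckd_code_config`.
#' @return Logical scalar.
#' @export
classify_ckd <- function(events, config = default_code_config()) {
  if (nrow(events) == 0) return(FALSE)
  check_event_sources(events)
  any(event_flags(events, config)$ckd_hit) || classify_advanced(events, config)
}

#' @rdname classify_ckd
#' @export
classify_advanced <- function(events, config = default_code_config()) {
  if (nrow(events) == 0) return(FALSE)
  check_event_sources(events)
  fl <- event_flags(events, config)
  dial_dates <- as_date_strict(events$date[fl$dialysis], "date")
  any(fl$transplant) || any(fl$adv_discharge) || any(fl$adv_drug) ||
    chronic_dialysis(dial_dates, config)
}

#' Apply the administrative algorithm to one subject
#'
#' Windows the events around the index date, evaluates the advanced
#' criteria first, then the generic CKD rule.
#'
#' @inheritParams classify_ckd
#' @param index_date The subject's index date.
#' @param window A [study_window()].
#' @return One of `"NO_CKD"`, `"CKD"`, `"ADVANCED_CKD"` (factor).
#' @export
apply_algorithm <- function(events, index_date, window = study_window(),
                            config = default_code_config()) {
  ev <- events_in_window(events, index_date, window)
  value <- if (nrow(ev) > 0 && classify_advanced(ev, config)) {
    "ADVANCED_CKD"
  } else if (nrow(ev) > 0 && classify_ckd(ev, config)) {
    "CKD"
  } else {
    "NO_CKD"
  }
  factor(value, levels = ckd_label_levels())
}

#' Classify every cohort subject from administrative events
#'
#' Vectorized version of [apply_algorithm()] over a cohort: events are
#' window-filtered per subject index date, criterion flags evaluated,
#' and every cohort subject receives a label (`NO_CKD` when no
#' qualifying event exists).
#'
#' @param events Tibble of events: `subject_id`, `date`, `source`, `code`.
#' @param cohort Tibble with `subject_id` and `index_date` (e.g. from
#'   [build_cohort()]).
#' @param window A [study_window()].
#' @param config A `ckd_code_config`.
#' @return Tibble `subject_id`, `al_label` with one row per cohort
#'   subject.
#' @export
classify_events <- function(events, cohort, window = study_window(),
                            config = default_code_config()) {
  check_columns(cohort, c("subject_id", "index_date"), "`cohort`")
  events <- as_tibble(events)
  if (nrow(events) > 0) check_event_sources(events)

  ev <- events_in_window(events, select(cohort, "subject_id", "index_date"), window)
  if (nrow(ev) > 0) {
    fl <- event_flags(ev, config)
    per_subject <- dplyr::bind_cols(select(ev, "subject_id", "date"), fl) %>%
      group_by(.data$subject_id) %>%
      summarise(
        advanced = any(.data$transplant) || any(.data$adv_discharge) ||
          any(.data$adv_drug) ||
          chronic_dialysis(.data$date[.data$dialysis], config),
        ckd = any(.data$ckd_hit) || advanced,
        .groups = "drop"
      )
  } else {
    per_subject <- tibble(
      subject_id = character(), advanced = logical(), ckd = logical()
    )
  }

  cohort %>%
    select("subject_id") %>%
    left_join(per_subject, by = "subject_id") %>%
    mutate(
      al_label = factor(
        case_when(
          dplyr::coalesce(.data$advanced, FALSE) ~ "ADVANCED_CKD",
          dplyr::coalesce(.data$ckd, FALSE) ~ "CKD",
          TRUE ~ "NO_CKD"
        ),
        levels = ckd_label_levels()
      )
    ) %>%
    select("subject_id", "al_label")
}

#' Read and write administrative events
#'
#' CSV schema: `subject_id`, `date` (ISO-8601), `source` (one of
#' hospital_discharge / exemption / outpatient_specialist /
#' drug_dispensing), `code`, and an optional `attributes` JSON column.
#'
#' @param path File path.
#' @return A tibble of events.
#' @export
read_events_csv <- function(path) {
  df <- readr::read_csv(path,
    col_types = readr::cols(
      subject_id = readr::col_character(),
      date = readr::col_date(),
      source = readr::col_character(),
      code = readr::col_character(),
      .default = readr::col_character()
    )
  )
  check_columns(df, c("subject_id", "date", "source", "code"), path)
  check_event_sources(df)
  df
}

#' @rdname read_events_csv
#' @param events Tibble of events.
#' @export
write_events_csv <- function(events, path) {
  readr::write_csv(events, path)
  invisible(path)
}
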