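# End-to-end orchestration: read (or accept) the three linked streams,
# compute eGFR, build the cohort, classify, and validate — for both
# positive definitions and both analysis variants.

resolve_input <- function(x, reader, what) {
  if (is.character(x) && length(x) == 1) {
    if (!file.exists(x)) {
      abort_input(sprintf("%s file not found: %s", what, x))
    }
    reader(x)
  } else if (is.data.frame(x)) {
    as_tibble(x)
  } else {
    abort_input(sprintf("`%s` must be a data frame or a file path.", what))
  }
}

check_linkage <- function(ids, subjects, what) {
  orphans <- setdiff(unique(ids), subjects$subject_id)
  if (length(orphans) > 0) {
    abort(
      sprintf(
        "%s reference %d subject id(s) absent from the subjects table: %s.",
        what, length(orphans), paste(head(orphans, 5), collapse = ", ")
      ),
      class = "ckdvalid_linkage_error"
    )
  }
}

#' Run the full validation pipeline
#'
#' Executes every stage on linked subject / creatinine / event streams:
#' eGFR computation (race-free CKD-EPI 2021), eligibility and
#' working-standard labelling, administrative classification, and
#' stratified diagnostic validation for both positive definitions. The
#' `outpatient_only` variant repeats eligibility, index-date selection
#' and labelling on the outpatient-restricted measurement series.
#'
#' @param subjects,creatinine,events Data frames, or paths to CSV files
#'   in the schemas of [read_subjects_csv()], [read_creatinine_csv()]
#'   and [read_events_csv()]. Every measurement and event subject id
#'   must exist in `subjects`.
#' @param code_config A `ckd_code_config`, or a YAML path.
#' @param window A [study_window()].
#' @param variants Analysis variants to run (`"main"`,
#'   `"outpatient_only"` or both).
#' @param ci_method Passed to [stratified_validation()].
#' @return An object of class `ckd_pipeline_result`: list with
#'   `reports` (named list of `ckd_validation`, one per variant),
#'   `cohort` (labelled main-variant cohort tibble), `attrition`
#'   (record counts in/out of each filter, per variant) and `manifest`.
#' @export
run_pipeline <- function(subjects, creatinine, events,
                         code_config = default_code_config(),
                         window = study_window(),
                         variants = c("main", "outpatient_only"),
                         ci_method = c("wald", "wilson")) {
  ci_method <- match.arg(ci_method)
  variants <- match.arg(variants, several.ok = TRUE)
  t0 <- Sys.time()

  subjects_df <- resolve_input(subjects, read_subjects_csv, "subjects")
  creatinine_df <- resolve_input(creatinine, read_creatinine_csv, "creatinine")
  events_df <- resolve_input(events, read_events_csv, "events")
  if (is.character(code_config)) code_config <- read_code_config(code_config)
  code_config <- validate_code_config(code_config)
  check_linkage(creatinine_df$subject_id, subjects_df, "Creatinine records")
  if (nrow(events_df) > 0) {
    check_event_sources(events_df)
    check_linkage(events_df$subject_id, subjects_df, "Administrative events")
  }

  scored <- add_egfr(creatinine_df, subjects_df)

  run_variant <- function(variant) {
    meas <- if (variant == "outpatient_only") restrict_outpatient(scored) else scored
    cohort <- build_cohort(subjects_df, meas, window)
    eligible <- filter(cohort, .data$eligible)
    al <- classify_events(events_df, eligible, window, code_config)
    labels <- left_join(eligible, al, by = "subject_id")
    report <- stratified_validation(labels,
      ci_method = ci_method, variant = variant
    )
    attrition <- tibble(
      variant = variant,
      stage = c(
        "subjects", "measurements", "in_window_subjects",
        "eligible", "ws_positive_ckd60"
      ),
      n = c(
        nrow(subjects_df), nrow(meas), sum(!is.na(cohort$index_date)),
        nrow(eligible),
        sum(label_is_positive(labels$ws_label, "ckd_60"))
      )
    )
    list(report = report, labels = labels, attrition = attrition)
  }

  runs <- setNames(lapply(variants, run_variant), variants)

  manifest <- list(
    package_version = as.character(utils::packageVersion("ckdvalid")),
    created = format(t0, "%Y-%m-%dT%H:%M:%S%z"),
    elapsed_s = round(as.numeric(difftime(Sys.time(), t0, units = "secs")), 3),
    window = list(
      start = format(window$start), end = format(window$end),
      lookback_years = window$lookback_years,
      lookahead_years = window$lookahead_years,
      chronicity_gap_days = window$chronicity_gap_days
    ),
    input_hashes = list(
      subjects = rlang::hash(subjects_df),
      creatinine = rlang::hash(creatinine_df),
      events = rlang::hash(events_df),
      code_config = rlang::hash(unclass(code_config))
    ),
    n_subjects = nrow(subjects_df),
    n_measurements = nrow(creatinine_df),
    n_events = nrow(events_df),
    ci_method = ci_method
  )

  structure(
    list(
      reports = purrr::map(runs, "report"),
      cohort = runs[[1]]$labels,
      attrition = bind_rows(purrr::map(runs, "attrition")),
      manifest = manifest
    ),
    class = "ckd_pipeline_result"
  )
}

#' @export
print.ckd_pipeline_result <- function(x, ...) {
  cat(sprintf(
    "<ckd_pipeline_result> %d subject(s), %d measurement(s), %d event(s)\n",
    x$manifest$n_subjects, x$manifest$n_measurements, x$manifest$n_events
  ))
  for (r in x$reports) print(r)
  invisible(x)
}

#' @method tidy ckd_pipeline_result
#' @export
tidy.ckd_pipeline_result <- function(x, ...) {
  bind_rows(purrr::imap(
    x$reports,
    function(r, v) mutate(tidy(r), variant = v)
  ))
}

#' Write all pipeline outputs
#'
#' Writes one TSV metric table per variant, a combined JSON report with
#' the embedded run manifest, and the labelled cohort CSV.
#'
#' @param result A `ckd_pipeline_result`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_pipeline_outputs <- function(result, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (v in names(result$reports)) {
    write_report_tsv(result$reports[[v]], file.path(dir, paste0("report_", v, ".tsv")))
  }
  write_report_json(result$reports, file.path(dir, "report.json"),
    manifest = result$manifest
  )
  write_cohort_csv(result$cohort, file.path(dir, "cohort.csv"))
  invisible(dir)
}
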