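# Independent brute-force oracles and small fixture builders. The
# oracles are deliberately literal (explicit loops over pairs/criteria)
# so they share no code path with the implementation they check.

make_meas <- function(days, egfr, origin = as.Date("2013-01-01"),
                      setting = "outpatient") {
  tibble::tibble(
    date = origin + days,
    egfr = egfr,
    setting = rep_len(setting, length(days))
  )
}

# literal re-statement of the working-standard definition: last value
# (same-day ties -> highest), plus any strictly earlier sub-60 value at
# least `gap` days back
oracle_ws_label <- function(days, egfr, gap = 90) {
  idx <- max(days)
  last_vals <- egfr[days == idx]
  L <- max(last_vals)
  chronic <- FALSE
  for (j in seq_along(days)) {
    if (egfr[j] < 60 && (idx - days[j]) >= gap) chronic <- TRUE
  }
  if (L < 30 && chronic) return("ADVANCED_CKD")
  if (L < 60 && chronic) return("CKD")
  "NO_CKD"
}

# eligibility gap criterion by full pair enumeration
oracle_gap_ok <- function(days, gap = 90) {
  if (length(days) < 2) return(FALSE)
  for (a in seq_along(days)) {
    for (b in seq_along(days)) {
      if (abs(days[a] - days[b]) >= gap) return(TRUE)
    }
  }
  FALSE
}

# literal enumeration of the administrative rules over one subject's
# events (already window-filtered)
oracle_classify <- function(events, config) {
  up <- function(x) toupper(trimws(x))
  pref <- function(code, pats) any(startsWith(up(code), up(pats)))
  adv <- FALSE
  for (i in seq_len(nrow(events))) {
    if (pref(events$code[i], config$transplant_codes)) adv <- TRUE
    if (events$source[i] == "hospital_discharge" &&
      pref(events$code[i], config$advanced_discharge_codes)) {
      adv <- TRUE
    }
    if (events$source[i] == "drug_dispensing" &&
      pref(events$code[i], config$advanced_drug_codes)) {
      adv <- TRUE
    }
  }
  dial <- events$date[vapply(
    events$code, function(cc) pref(cc, config$dialysis_codes), TRUE
  )]
  if (length(dial) >= config$chronic_dialysis_min_events) {
    for (a in seq_along(dial)) {
      for (b in seq_along(dial)) {
        if (as.numeric(dial[a] - dial[b]) >= config$chronic_dialysis_min_span_days) {
          adv <- TRUE
        }
      }
    }
  }
  ckd <- adv
  for (i in seq_len(nrow(events))) {
    pats <- config$ckd_codes[[events$source[i]]]
    if (!is.null(pats) && pref(events$code[i], pats)) ckd <- TRUE
  }
  list(ckd = ckd, advanced = adv)
}

# random event-set generator around the active config, mixing matching
# and non-matching codes
random_events <- function(n, config, origin = as.Date("2013-06-01")) {
  sources <- c(
    "hospital_discharge", "exemption", "outpatient_specialist",
    "drug_dispensing"
  )
  pool <- c(
    unlist(config$ckd_codes), config$dialysis_codes, config$transplant_codes,
    config$advanced_discharge_codes, config$advanced_drug_codes,
    "428.0", "J01CA04", "999", "C03CA01"
  )
  tibble::tibble(
    subject_id = "sX",
    date = origin + sample.int(2000, n, replace = TRUE) - 1000,
    source = sample(sources, n, replace = TRUE),
    code = sample(pool, n, replace = TRUE)
  )
}

full_residency <- "1900-01-01/2030-12-31"

# bisection oracle for the inverse eGFR map (independent of the
# closed-form inverse under test)
bisect_scr <- function(target, age, sex, lo = 0.05, hi = 25, tol = 1e-12) {
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (egfr_ckd_epi(mid, age, sex) > target) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}
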