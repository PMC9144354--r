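# Cohort building: index dates, eligibility, working-standard labels.

test_that("index date is the last in-window measurement", {
  win <- study_window()
  expect_equal(
    select_index_date(as.Date(c("2012-03-01", "2014-06-15")), win),
    as.Date("2014-06-15")
  )
  expect_equal(
    select_index_date(as.Date("2013-01-01"), win),
    as.Date("2013-01-01")
  )
  expect_error(
    select_index_date(as.Date("2016-05-01"), win),
    class = "ckdvalid_not_eligible"
  )
})

test_that("eligibility applies gap, age and residency criteria with reason codes", {
  win <- study_window()
  subj <- list(birth_date = as.Date("1967-05-01"), residency = full_residency)

  two_close <- make_meas(c(0, 89), c(70, 70), origin = as.Date("2012-02-01"))
  r <- is_eligible(subj, two_close, win)
  expect_false(r$eligible)
  expect_equal(r$reasons, "gap")

  ok <- make_meas(c(0, 121), c(70, 70), origin = as.Date("2012-02-01"))
  r2 <- is_eligible(subj, ok, win)
  expect_true(r2$eligible)
  expect_length(r2$reasons, 0)

  # 18 years 11 months at index -> too young
  young <- list(birth_date = as.Date("1994-07-01"), residency = full_residency)
  r3 <- is_eligible(young, make_meas(c(0, 120), c(70, 70),
    origin = as.Date("2013-02-01")
  ), win)
  expect_false(r3$eligible)
  expect_true("age" %in% r3$reasons)

  # residency hole inside the lookback
  gappy <- list(
    birth_date = as.Date("1960-01-01"),
    residency = "1960-01-01/2011-06-01;2011-09-01/2030-01-01"
  )
  r4 <- is_eligible(gappy, ok, win)
  expect_false(r4$eligible)
  expect_equal(r4$reasons, "residency")
})

test_that("abutting residency intervals count as continuous coverage", {
  subj <- list(
    birth_date = as.Date("1960-01-01"),
    residency = "1960-01-01/2013-06-30;2013-06-30/2030-01-01"
  )
  m <- make_meas(c(0, 150), c(70, 70), origin = as.Date("2013-01-01"))
  expect_true(is_eligible(subj, m)$eligible)
})

test_that("residency strings parse, serialize and reject malformed input", {
  s <- "2000-01-01/2010-12-31;2011-06-01/2020-01-01"
  iv <- parse_residency(s)
  expect_equal(nrow(iv), 2)
  expect_equal(format_residency(iv), s)
  expect_error(parse_residency("2000-01-01"), "pairs")
  expect_error(parse_residency("2010-01-01/2005-01-01"), "exceed")
  expect_error(parse_residency("2000-01-01/2010-01-01;2005-01-01/2012-01-01"), "overlap")
})

test_that("working-standard labels follow the last-value + chronicity rule", {
  origin <- as.Date("2013-01-01")
  cases <- list(
    list(d = c(0, 100), e = c(55, 52), want = "CKD"),
    list(d = c(0, 120), e = c(55, 25), want = "ADVANCED_CKD"),
    list(d = c(0, 120), e = c(55, 65), want = "NO_CKD"),
    list(d = c(0, 30, 60), e = c(75, 58, 55), want = "NO_CKD")
  )
  for (cs in cases) {
    m <- make_meas(cs$d, cs$e, origin)
    expect_equal(
      as.character(working_standard_label(m, origin + max(cs$d))),
      cs$want
    )
  }
  expect_error(
    working_standard_label(make_meas(0, 50, origin), origin + 5),
    class = "ckdvalid_internal_error"
  )
})

test_that("same-day duplicates at the index date keep the highest eGFR", {
  origin <- as.Date("2013-01-01")
  m <- make_meas(c(0, 120, 120), c(55, 25, 65), origin)
  expect_equal(as.character(working_standard_label(m, origin + 120)), "NO_CKD")
  m2 <- make_meas(c(0, 120, 120), c(55, 25, 55), origin)
  expect_equal(as.character(working_standard_label(m2, origin + 120)), "CKD")
})

test_that("labels and eligibility agree with brute-force enumeration", {
  set.seed(301)
  for (i in 1:250) {
    n <- sample(1:6, 1)
    days <- sort(sample(0:400, n))
    egfr <- runif(n, 20, 80)
    origin <- as.Date("2012-06-01")
    m <- make_meas(days, egfr, origin)
    expect_equal(
      as.character(working_standard_label(m, origin + max(days))),
      oracle_ws_label(days, egfr)
    )
    subj <- list(birth_date = as.Date("1955-01-01"), residency = full_residency)
    r <- is_eligible(subj, m)
    expect_equal(r$eligible, oracle_gap_ok(days))
  }
})

test_that("labels are invariant to permutation of record order", {
  set.seed(302)
  origin <- as.Date("2013-01-01")
  for (i in 1:25) {
    n <- sample(2:6, 1)
    days <- sort(sample(0:400, n))
    egfr <- runif(n, 20, 80)
    m <- make_meas(days, egfr, origin)
    shuffled <- m[sample.int(n), ]
    expect_equal(
      working_standard_label(m, origin + max(days)),
      working_standard_label(shuffled, origin + max(days))
    )
  }
})

test_that("restrict_outpatient filters exactly the outpatient records", {
  m <- make_meas(1:5, 60 + 1:5,
    setting = c("inpatient", "outpatient", "outpatient", "emergency", "outpatient")
  )
  expect_equal(nrow(restrict_outpatient(m)), 3)
  expect_equal(nrow(restrict_outpatient(m[m$setting == "inpatient", ])), 0)
  all_out <- make_meas(1:3, c(70, 70, 70))
  expect_identical(restrict_outpatient(all_out), all_out)
})

test_that("build_cohort matches the single-subject operations", {
  set.seed(303)
  n <- 60
  subjects <- tibble::tibble(
    subject_id = sprintf("p%02d", 1:n),
    sex = sample(c("male", "female"), n, replace = TRUE),
    birth_date = as.Date("1950-01-01") + sample.int(15000, n),
    residency = ifelse(runif(n) < 0.15,
      "1940-01-01/2012-06-01;2012-10-01/2030-01-01",
      full_residency
    )
  )
  recs <- purrr::map_dfr(seq_len(n), function(i) {
    k <- sample(0:6, 1)
    if (k == 0) return(NULL)
    days <- sort(sample(0:1000, k))
    tibble::tibble(
      subject_id = subjects$subject_id[i],
      date = as.Date("2012-02-01") + days,
      egfr = runif(k, 15, 90)
    )
  })
  win <- study_window()
  cohort <- build_cohort(subjects, recs, win)
  expect_equal(nrow(cohort), n)
  for (i in seq_len(n)) {
    m <- recs[recs$subject_id == subjects$subject_id[i], ]
    m <- m[m$date >= win$start & m$date <= win$end, ]
    row <- cohort[cohort$subject_id == subjects$subject_id[i], ]
    el <- is_eligible(as.list(subjects[i, ]), m, win)
    expect_equal(row$eligible, el$eligible)
    if (el$eligible) {
      idx <- select_index_date(m$date, win)
      expect_equal(row$index_date, idx)
      expect_equal(
        as.character(row$ws_label),
        as.character(working_standard_label(m, idx, win$chronicity_gap_days))
      )
    } else {
      expect_true(is.na(row$ws_label))
    }
  }
})
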