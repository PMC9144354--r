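# 2x2 tables, validity metrics, confidence intervals, stratification.

test_that("contingency tables count paired labels under both definitions", {
  labels <- tibble::tibble(
    ws_label = c("CKD", "ADVANCED_CKD", "NO_CKD", "NO_CKD", "CKD", "ADVANCED_CKD"),
    al_label = c("CKD", "NO_CKD", "CKD", "NO_CKD", "NO_CKD", "ADVANCED_CKD")
  )
  ct <- build_contingency(labels, "ckd_60")
  expect_equal(c(ct$tp, ct$fp, ct$fn, ct$tn), c(2, 1, 2, 1))
  # CKD-but-not-advanced is negative on both axes for advanced_30
  cta <- build_contingency(labels, "advanced_30")
  expect_equal(c(cta$tp, cta$fp, cta$fn, cta$tn), c(1, 0, 1, 4))
  expect_equal(ct$n, nrow(labels))
})

test_that("degenerate tables behave: all-negative and perfect agreement", {
  neg <- tibble::tibble(ws_label = rep("NO_CKD", 5), al_label = rep("NO_CKD", 5))
  ctn <- build_contingency(neg)
  expect_equal(c(ctn$tp, ctn$fp, ctn$fn, ctn$tn), c(0, 0, 0, 5))
  agree <- tibble::tibble(
    ws_label = c("CKD", "NO_CKD", "ADVANCED_CKD"),
    al_label = c("CKD", "NO_CKD", "ADVANCED_CKD")
  )
  cta <- build_contingency(agree)
  expect_equal(cta$fp + cta$fn, 0)
  expect_error(
    build_contingency(tibble::tibble(ws_label = c("CKD", NA), al_label = c("CKD", "CKD"))),
    class = "ckdvalid_alignment_error"
  )
})

test_that("metric identities hold exactly on unrounded estimates", {
  set.seed(501)
  for (i in 1:20) {
    cts <- sample.int(2000, 4)
    ct <- contingency_table(cts[1], cts[2], cts[3], cts[4])
    m <- diagnostic_metrics(ct)
    sens <- m$estimate[m$metric == "sensitivity"]
    expect_equal(sens * (ct$tp + ct$fn), 100 * ct$tp, tolerance = 1e-9)
    spec <- m$estimate[m$metric == "specificity"]
    expect_equal(spec * (ct$tn + ct$fp), 100 * ct$tn, tolerance = 1e-9)
    ppv <- m$estimate[m$metric == "ppv"]
    expect_equal(ppv * (ct$tp + ct$fp), 100 * ct$tp, tolerance = 1e-9)
    npv <- m$estimate[m$metric == "npv"]
    expect_equal(npv * (ct$tn + ct$fn), 100 * ct$tn, tolerance = 1e-9)
  }
})

test_that("tp = fn gives sensitivity of exactly 50%", {
  m <- diagnostic_metrics(contingency_table(37, 5, 37, 100))
  expect_equal(m$estimate[m$metric == "sensitivity"], 50)
})

test_that("Wald interval matches the closed form and clips at the scale ends", {
  ct <- contingency_table(80, 10, 20, 200)
  m <- diagnostic_metrics(ct, ci_method = "wald")
  p <- 80 / 100
  half <- qnorm(0.975) * sqrt(p * (1 - p) / 100)
  sens <- m[m$metric == "sensitivity", ]
  expect_equal(sens$conf_low, 100 * (p - half), tolerance = 1e-12)
  expect_equal(sens$conf_high, 100 * (p + half), tolerance = 1e-12)
  # zero numerator: lower bound clipped at 0
  z <- diagnostic_metrics(contingency_table(0, 0, 10, 90))
  expect_equal(z$estimate[z$metric == "sensitivity"], 0)
  expect_equal(z$conf_low[z$metric == "sensitivity"], 0)
  expect_equal(z$conf_high[z$metric == "specificity"], 100)
})

test_that("Wilson interval agrees with score-test inversion", {
  # oracle: the Wilson bounds are the roots of the score statistic
  score_bounds <- function(x, n, z = qnorm(0.975)) {
    f <- function(p0) (x / n - p0)^2 - z^2 * p0 * (1 - p0) / n
    lo <- if (x == 0) 0 else stats::uniroot(f, c(1e-12, x / n), tol = 1e-12)$root
    hi <- if (x == n) 1 else stats::uniroot(f, c(x / n, 1 - 1e-12), tol = 1e-12)$root
    c(lo, hi)
  }
  for (case in list(c(80, 100), c(3, 40), c(1724, 3384))) {
    ct <- contingency_table(case[1], 0, case[2] - case[1], 50)
    m <- diagnostic_metrics(ct, ci_method = "wilson")
    sens <- m[m$metric == "sensitivity", ]
    oracle <- 100 * score_bounds(case[1], case[2])
    expect_equal(sens$conf_low, oracle[1], tolerance = 1e-6)
    expect_equal(sens$conf_high, oracle[2], tolerance = 1e-6)
  }
})

test_that("zero denominators are flagged undefined, not dropped", {
  m <- diagnostic_metrics(contingency_table(0, 0, 0, 50))
  sens <- m[m$metric == "sensitivity", ]
  expect_true(sens$undefined)
  expect_true(is.na(sens$estimate))
  expect_equal(nrow(m), 6) # all metrics still present
})

test_that("prevalence uses the requested label source", {
  labels <- tibble::tibble(
    ws_label = c("CKD", "NO_CKD", "ADVANCED_CKD", "NO_CKD"),
    al_label = c("NO_CKD", "NO_CKD", "ADVANCED_CKD", "CKD")
  )
  expect_equal(prevalence(labels, "ckd_60", "working_standard")$estimate, 50)
  expect_equal(prevalence(labels, "advanced_30", "algorithm")$estimate, 25)
  expect_error(prevalence(labels[0, ]), "empty")
})

test_that("stratified validation is additive and validates stratum values", {
  set.seed(502)
  n <- 400
  labels <- tibble::tibble(
    subject_id = sprintf("x%03d", 1:n),
    sex = sample(c("male", "female"), n, replace = TRUE),
    age_class = sample(c("19-44", "45-64", "65-74"), n, replace = TRUE),
    ws_label = sample(c("NO_CKD", "CKD", "ADVANCED_CKD"), n,
      replace = TRUE, prob = c(0.8, 0.15, 0.05)
    ),
    al_label = sample(c("NO_CKD", "CKD", "ADVANCED_CKD"), n,
      replace = TRUE, prob = c(0.85, 0.1, 0.05)
    )
  )
  rep <- stratified_validation(labels)
  counts <- rep$counts
  for (def in c("ckd_60", "advanced_30")) {
    ov <- counts[counts$stratum_type == "overall" &
      counts$positive_definition == def, ]
    for (s in c("sex", "age_class")) {
      part <- counts[counts$stratum_type == s &
        counts$positive_definition == def, ]
      expect_equal(sum(part$tp), ov$tp)
      expect_equal(sum(part$fp), ov$fp)
      expect_equal(sum(part$fn), ov$fn)
      expect_equal(sum(part$tn), ov$tn)
    }
  }
  expect_s3_class(tidy(rep), "tbl_df")
  expect_true(all(c("sensitivity", "specificity", "ppv", "npv") %in%
    glance(rep) %>% names()))

  labels$sex[3] <- NA
  expect_error(stratified_validation(labels), class = "ckdvalid_validation_error")
})

test_that("autoplot returns a ggplot of the metric estimates", {
  p <- ggplot2::autoplot(worked_example_report())
  expect_s3_class(p, "ggplot")
})

test_that("round_half_up rounds ties away from zero", {
  expect_equal(round_half_up(c(50.95, 50.94, 0.05, -1.25), 1),
               c(51.0, 50.9, 0.1, -1.3))
})
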