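# Diagnostic-accuracy statistics: 2x2 tables of algorithm vs working
# standard, sensitivity/specificity/PPV/NPV/prevalence with 95% CIs,
# stratified by sex and age class. All identities are evaluated on
# unrounded proportions; percent formatting happens only at reporting.

positive_definitions <- function() c("ckd_60", "advanced_30")

label_is_positive <- function(label, positive_definition) {
  label <- as.character(label)
  switch(positive_definition,
    ckd_60 = label %in% c("CKD", "ADVANCED_CKD"),
    advanced_30 = label == "ADVANCED_CKD",
    abort_input(sprintf("Unknown positive definition '%s'.", positive_definition))
  )
}

#' Construct a 2x2 contingency table
#'
#' @param tp,fp,fn,tn Non-negative counts (algorithm vs working
#'   standard: true/false positives/negatives).
#' @param positive_definition `"ckd_60"` (positive = any CKD-range label,
#'   eGFR < 60 threshold) or `"advanced_30"` (positive = advanced CKD
#'   only, eGFR < 30 threshold; CKD-but-not-advanced counts as negative
#'   on both axes).
#' @return An object of class `ckd_contingency`.
#' @export
#' @examples
#' contingency_table(tp = 1724, fp = 949, fn = 1660, tn = 26160)
contingency_table <- function(tp, fp, fn, tn, positive_definition = "ckd_60") {
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (anyNA(counts) || any(counts < 0) || any(counts != round(counts))) {
    abort_input("Contingency counts must be non-negative integers.")
  }
  check_choice(positive_definition, positive_definitions(), "positive_definition")
  structure(
    list(
      tp = as.numeric(tp), fp = as.numeric(fp),
      fn = as.numeric(fn), tn = as.numeric(tn),
      n = as.numeric(tp + fp + fn + tn),
      positive_definition = positive_definition
    ),
    class = "ckd_contingency"
  )
}

#' @export
print.ckd_contingency <- function(x, ...) {
  cat(sprintf(
    "<ckd_contingency: %s, n = %s>\n            WS+      WS-\n  AL+  %8d %8d\n  AL-  %8d %8d\n",
    x$positive_definition, format(x$n, big.mark = ","),
    x$tp, x$fp, x$fn, x$tn
  ))
  invisible(x)
}

#' @method tidy ckd_contingency
#' @export
tidy.ckd_contingency <- function(x, ...) {
  tibble(
    positive_definition = x$positive_definition,
    tp = x$tp, fp = x$fp, fn = x$fn, tn = x$tn, n = x$n
  )
}

#' Build a contingency table from paired labels
#'
#' Cross-tabulates working-standard against algorithm labels for aligned
#' subjects under a positive definition.
#'
#' @param labels Data frame with `ws_label` and `al_label` columns (and
#'   any identifying columns); one row per subject, no missing labels.
#' @param positive_definition See [contingency_table()].
#' @return A `ckd_contingency`.
#' @export
build_contingency <- function(labels, positive_definition = "ckd_60") {
  check_columns(labels, c("ws_label", "al_label"), "`labels`")
  if (anyNA(labels$ws_label) || anyNA(labels$al_label)) {
    abort(
      "Labels contain missing values; working standard and algorithm must cover the same subjects.",
      class = "ckdvalid_alignment_error"
    )
  }
  ws <- label_is_positive(labels$ws_label, positive_definition)
  al <- label_is_positive(labels$al_label, positive_definition)
  contingency_table(
    tp = sum(ws & al), fp = sum(!ws & al),
    fn = sum(ws & !al), tn = sum(!ws & !al),
    positive_definition = positive_definition
  )
}

# ---- confidence intervals ---------------------------------------------------

# Wald and Wilson intervals for a binomial proportion, on the [0, 1]
# scale, clipped to [0, 1]. Wald is the default because it is the
# interval conventionally reported alongside validity metrics in
# record-linkage validation studies.
prop_ci <- function(x, n, method = c("wald", "wilson"), conf_level = 0.95) {
  method <- match.arg(method)
  z <- qnorm(1 - (1 - conf_level) / 2)
  p <- x / n
  if (method == "wald") {
    half <- z * sqrt(p * (1 - p) / n)
    lo <- p - half
    hi <- p + half
  } else {
    denom <- 1 + z^2 / n
    centre <- (p + z^2 / (2 * n)) / denom
    half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
    lo <- centre - half
    hi <- centre + half
  }
  c(low = max(0, lo), high = min(1, hi))
}

metric_row <- function(name, num, den, ci_method, conf_level) {
  if (is.na(den) || den == 0) {
    return(tibble(
      metric = name, numerator = num, denominator = den,
      estimate = NA_real_, conf_low = NA_real_, conf_high = NA_real_,
      undefined = TRUE
    ))
  }
  ci <- prop_ci(num, den, ci_method, conf_level)
  tibble(
    metric = name, numerator = num, denominator = den,
    estimate = 100 * num / den,
    conf_low = 100 * ci[["low"]], conf_high = 100 * ci[["high"]],
    undefined = FALSE
  )
}

#' Diagnostic-accuracy metrics from a 2x2 table
#'
#' Sensitivity tp/(tp+fn), specificity tn/(tn+fp), PPV tp/(tp+fp),
#' NPV tn/(tn+fn), and optionally working-standard and algorithm
#' prevalence, each with a 95% confidence interval, on the percent
#' scale (unrounded; use [round_half_up()] for one-decimal reporting).
#' A metric with a zero denominator is returned with `undefined = TRUE`
#' rather than dropped.
#'
#' @param ct A `ckd_contingency`.
#' @param ci_method `"wald"` (default) or `"wilson"`.
#' @param conf_level Confidence level (default 0.95).
#' @param include_prevalence Also return `ws_prevalence` ((tp+fn)/n) and
#'   `al_prevalence` ((tp+fp)/n) rows.
#' @return A tibble with columns `metric`, `numerator`, `denominator`,
#'   `estimate`, `conf_low`, `conf_high`, `undefined`.
#' @export
#' @examples
#' diagnostic_metrics(contingency_table(1724, 949, 1660, 26160))
diagnostic_metrics <- function(ct, ci_method = c("wald", "wilson"),
                               conf_level = 0.95, include_prevalence = TRUE) {
  stopifnot(inherits(ct, "ckd_contingency"))
  ci_method <- match.arg(ci_method)
  out <- bind_rows(
    metric_row("sensitivity", ct$tp, ct$tp + ct$fn, ci_method, conf_level),
    metric_row("specificity", ct$tn, ct$tn + ct$fp, ci_method, conf_level),
    metric_row("ppv", ct$tp, ct$tp + ct$fp, ci_method, conf_level),
    metric_row("npv", ct$tn, ct$tn + ct$fn, ci_method, conf_level)
  )
  if (include_prevalence) {
    out <- bind_rows(
      out,
      metric_row("ws_prevalence", ct$tp + ct$fn, ct$n, ci_method, conf_level),
      metric_row("al_prevalence", ct$tp + ct$fp, ct$n, ci_method, conf_level)
    )
  }
  out
}

#' Prevalence of a label in a cohort
#'
#' @param labels Data frame of labels.
#' @param positive_definition See [contingency_table()].
#' @param source Which label column to use: working standard
#'   (`ws_label`) or algorithm (`al_label`).
#' @inheritParams diagnostic_metrics
#' @return A one-row metric tibble (percent scale).
#' @export
prevalence <- function(labels, positive_definition = "ckd_60",
                       source = c("working_standard", "algorithm"),
                       ci_method = c("wald", "wilson"), conf_level = 0.95) {
  source <- match.arg(source)
  ci_method <- match.arg(ci_method)
  col <- if (source == "working_standard") "ws_label" else "al_label"
  check_columns(labels, col, "`labels`")
  if (nrow(labels) == 0) abort_input("Cannot compute prevalence of an empty cohort.")
  pos <- label_is_positive(labels[[col]], positive_definition)
  metric_row("prevalence", sum(pos), length(pos), ci_method, conf_level)
}

# ---- stratified validation --------------------------------------------------

#' Stratified diagnostic validation
#'
#' Builds overall and per-stratum 2x2 tables of the algorithm against
#' the working standard, for each positive definition, and computes all
#' validity metrics. Stratum tables sum to the overall table by
#' construction; this is asserted before returning.
#'
#' @param labels Data frame with `subject_id`, `ws_label`, `al_label`
#'   and the stratification columns (default `sex`, `age_class`).
#' @param strata Character vector of stratification columns.
#' @param definitions Positive definitions to evaluate.
#' @param ci_method,conf_level Passed to [diagnostic_metrics()].
#' @param variant Analysis variant tag stored in the report (e.g.
#'   `"main"` or `"outpatient_only"`).
#' @return An object of class `ckd_validation`: list with `counts`
#'   (tibble of per-stratum 2x2 counts), `metrics` (tidy metric tibble),
#'   `ci_method`, `variant`, `n`.
#' @export
stratified_validation <- function(labels, strata = c("sex", "age_class"),
                                  definitions = positive_definitions(),
                                  ci_method = c("wald", "wilson"),
                                  conf_level = 0.95, variant = "main") {
  ci_method <- match.arg(ci_method)
  check_columns(labels, c("subject_id", "ws_label", "al_label", strata), "`labels`")
  for (s in strata) {
    if (anyNA(labels[[s]])) {
      bad <- labels$subject_id[is.na(labels[[s]])]
      abort(
        sprintf(
          "Missing `%s` for %d subject(s): %s.",
          s, length(bad), paste(head(bad, 5), collapse = ", ")
        ),
        class = "ckdvalid_validation_error"
      )
    }
  }

  strata_of <- function(df, stratum_type, stratum) {
    purrr::map(definitions, function(def) {
      ct <- build_contingency(df, def)
      tidy(ct) %>%
        mutate(
          stratum_type = stratum_type, stratum = stratum,
          metrics = list(diagnostic_metrics(ct, ci_method, conf_level))
        )
    }) %>%
      bind_rows()
  }

  counts <- strata_of(labels, "overall", "overall")
  for (s in strata) {
    for (v in levels(factor(labels[[s]]))) {
      counts <- bind_rows(
        counts,
        strata_of(labels[labels[[s]] == v, , drop = FALSE], s, v)
      )
    }
  }

  # strata additivity check: each stratum type partitions the cohort
  for (def in definitions) {
    overall_n <- counts$n[counts$stratum_type == "overall" &
      counts$positive_definition == def]
    for (s in strata) {
      part <- sum(counts$n[counts$stratum_type == s &
        counts$positive_definition == def])
      if (part != overall_n) {
        abort(sprintf("Stratum tables for `%s` do not sum to the overall table.", s),
          class = "ckdvalid_internal_error"
        )
      }
    }
  }

  metrics <- counts %>%
    select("positive_definition", "stratum_type", "stratum", "metrics") %>%
    tidyr::unnest("metrics")

  structure(
    list(
      counts = select(counts, -"metrics"),
      metrics = metrics,
      ci_method = ci_method, conf_level = conf_level,
      variant = variant, n = nrow(labels)
    ),
    class = "ckd_validation"
  )
}

#' @export
print.ckd_validation <- function(x, ...) {
  cat(sprintf(
    "<ckd_validation> variant = %s, n = %s, CI = %s %d%%\n",
    x$variant, format(x$n, big.mark = ","), x$ci_method,
    round(100 * x$conf_level)
  ))
  ov <- x$metrics %>%
    filter(.data$stratum_type == "overall", !.data$undefined) %>%
    mutate(
      txt = sprintf(
        "%s %.1f (%.1f, %.1f)", .data$metric,
        round_half_up(.data$estimate), round_half_up(.data$conf_low),
        round_half_up(.data$conf_high)
      )
    )
  for (def in unique(ov$positive_definition)) {
    cat(" ", def, ": ",
      paste(ov$txt[ov$positive_definition == def], collapse = "; "), "\n",
      sep = ""
    )
  }
  invisible(x)
}

#' Tidy a stratified validation report
#'
#' @param x A `ckd_validation`.
#' @param ... Unused.
#' @return Tibble of metrics: one row per definition, stratum and
#'   metric, with percent-scale estimates and CI bounds.
#' @method tidy ckd_validation
#' @export
tidy.ckd_validation <- function(x, ...) {
  x$metrics
}

#' @method glance ckd_validation
#' @export
glance.ckd_validation <- function(x, ...) {
  x$metrics %>%
    filter(.data$stratum_type == "overall") %>%
    select("positive_definition", "metric", "estimate") %>%
    tidyr::pivot_wider(names_from = "metric", values_from = "estimate") %>%
    mutate(variant = x$variant, n = x$n, ci_method = x$ci_method)
}

#' Plot a validation report
#'
#' Point estimates with confidence intervals for every metric, by
#' stratum, faceted by positive definition.
#'
#' @param object A `ckd_validation`.
#' @param metrics Which metrics to display.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ckd_validation
#' @export
autoplot.ckd_validation <- function(object,
                                    metrics = c(
                                      "sensitivity", "specificity",
                                      "ppv", "npv"
                                    ), ...) {
  df <- object$metrics %>%
    filter(.data$metric %in% metrics, !.data$undefined) %>%
    mutate(
      stratum = factor(.data$stratum, levels = unique(.data$stratum)),
      metric = factor(.data$metric, levels = metrics)
    )
  ggplot2::ggplot(
    df,
    ggplot2::aes(
      x = .data$estimate, y = .data$stratum, colour = .data$metric
    )
  ) +
    ggplot2::geom_pointrange(
      ggplot2::aes(xmin = .data$conf_low, xmax = .data$conf_high),
      position = ggplot2::position_dodge(width = 0.6)
    ) +
    ggplot2::facet_wrap(~positive_definition) +
    ggplot2::labs(
      x = "Estimate (%)", y = NULL, colour = NULL,
      title = sprintf("Algorithm validity vs working standard (%s)", object$variant)
    ) +
    ggplot2::xlim(0, 100) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Write a validation report
#'
#' `write_report_tsv()` writes the tidy metric table (metric, point,
#' CI bounds per stratum); `write_report_json()` writes the full report
#' including counts and, when supplied, a run manifest.
#'
#' @param report A `ckd_validation` (or list of them).
#' @param path Output file path.
#' @param manifest Optional manifest list to embed (JSON only).
#' @export
write_report_tsv <- function(report, path) {
  stopifnot(inherits(report, "ckd_validation"))
  readr::write_tsv(
    report$metrics %>%
      mutate(dplyr::across(
        c("estimate", "conf_low", "conf_high"),
        ~ round_half_up(.x, 1)
      )),
    path
  )
  invisible(path)
}

#' @rdname write_report_tsv
#' @export
write_report_json <- function(report, path, manifest = NULL) {
  to_list <- function(r) {
    list(
      variant = r$variant, n = r$n, ci_method = r$ci_method,
      conf_level = r$conf_level, counts = r$counts, metrics = r$metrics
    )
  }
  payload <- if (inherits(report, "ckd_validation")) {
    to_list(report)
  } else {
    purrr::map(report, to_list)
  }
  if (!is.null(manifest)) payload <- list(manifest = manifest, report = payload)
  jsonlite::write_json(payload, path,
    dataframe = "rows", auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(path)
}
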