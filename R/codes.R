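# Code-set configuration for the administrative classifier.
#
# The shipped defaults are *synthetic placeholders* shaped like ICD-9-CM
# and ATC hierarchies (585.x-style discharge codes, B03XA/V03AE-style
# drug prefixes). Real deployments load region-specific lists from YAML;
# every synthetic cohort in this package emits codes drawn from the
# active config, so results are config-consistent by construction.

admin_sources <- function() {
  c("hospital_discharge", "exemption", "outpatient_specialist", "drug_dispensing")
}

#' Default administrative code-set configuration
#'
#' Returns the classifier's code-set configuration: per-source CKD code
#' prefixes plus the four advanced-CKD criteria (chronic dialysis,
#' kidney transplant, G4+ discharge diagnosis, selected drugs —
#' erythropoiesis-stimulating agents, potassium and phosphate binders).
#' Matching is case-insensitive exact-prefix, mirroring how ICD-9-CM and
#' ATC codes nest. The shipped lists are documented placeholders, not a
#' reproduction of any regional registry's operational lists.
#'
#' @return A list of class `ckd_code_config` with elements `ckd_codes`
#'   (named list, one character vector of prefixes per source),
#'   `dialysis_codes`, `transplant_codes`, `advanced_discharge_codes`,
#'   `advanced_drug_codes`, `chronic_dialysis_min_events` (default 2)
#'   and `chronic_dialysis_min_span_days` (default 90).
#' @export
#' @examples
#' cfg <- default_code_config()
#' cfg$advanced_drug_codes
default_code_config <- function() {
  validate_code_config(list(
    ckd_codes = list(
      hospital_discharge = c("585", "586"),
      exemption = c("023"),
      outpatient_specialist = c("39.95"),
      drug_dispensing = c("B03XA")
    ),
    dialysis_codes = c("39.95", "54.98"),
    transplant_codes = c("55.69", "V42.0"),
    advanced_discharge_codes = c("585.4", "585.5", "585.6"),
    advanced_drug_codes = c(
      "B03XA01", # erythropoietin
      "B03XA02", # darbepoetin alfa
      "B03XA03", # methoxy polyethylene glycol-epoetin beta
      "V03AE01", # polystyrene sulfonate
      "V03AE02", # sevelamer
      "V03AE03", # lanthanum carbonate
      "V03AE05"  # sucroferric oxyhydroxide
    ),
    chronic_dialysis_min_events = 2L,
    chronic_dialysis_min_span_days = 90
  ))
}

#' Validate a code-set configuration
#'
#' @param config A list with the [default_code_config()] schema.
#' @return The validated config, classed `ckd_code_config`.
#' @export
validate_code_config <- function(config) {
  if (!is.list(config)) abort_input("Code config must be a list.")
  required <- c(
    "ckd_codes", "dialysis_codes", "transplant_codes",
    "advanced_discharge_codes", "advanced_drug_codes",
    "chronic_dialysis_min_events", "chronic_dialysis_min_span_days"
  )
  missing <- setdiff(required, names(config))
  if (length(missing) > 0) {
    abort_input(sprintf(
      "Code config is missing field(s): %s.", paste(missing, collapse = ", ")
    ))
  }
  if (!is.list(config$ckd_codes) || length(config$ckd_codes) == 0) {
    abort_input("`ckd_codes` must be a non-empty named list (source -> prefixes).")
  }
  bad_src <- setdiff(names(config$ckd_codes), admin_sources())
  if (length(bad_src) > 0) {
    abort_input(sprintf(
      "`ckd_codes` names unknown source(s): %s. Known sources: %s.",
      paste(bad_src, collapse = ", "), paste(admin_sources(), collapse = ", ")
    ))
  }
  for (f in c("dialysis_codes", "transplant_codes", "advanced_discharge_codes",
              "advanced_drug_codes")) {
    if (!is.character(config[[f]]) || length(config[[f]]) == 0 ||
      any(!nzchar(config[[f]]))) {
      abort_input(sprintf("`%s` must be a non-empty character vector.", f))
    }
  }
  if (!is.numeric(config$chronic_dialysis_min_events) ||
    config$chronic_dialysis_min_events < 1) {
    abort_input("`chronic_dialysis_min_events` must be >= 1.")
  }
  if (!is.numeric(config$chronic_dialysis_min_span_days) ||
    config$chronic_dialysis_min_span_days < 0) {
    abort_input("`chronic_dialysis_min_span_days` must be non-negative.")
  }
  config$ckd_codes <- lapply(config$ckd_codes, as.character)
  structure(config, class = "ckd_code_config")
}

#' Read / write a code-set configuration (YAML)
#'
#' @param path YAML file path.
#' @return `read_code_config()`: a validated `ckd_code_config`.
#' @export
read_code_config <- function(path) {
  validate_code_config(yaml::read_yaml(path))
}

#' @rdname read_code_config
#' @param config A `ckd_code_config`.
#' @export
write_code_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

# case-insensitive exact-prefix match of codes against any pattern
match_prefix <- function(codes, patterns) {
  codes <- toupper(trimws(as.character(codes)))
  patterns <- toupper(trimws(patterns))
  out <- rep(FALSE, length(codes))
  for (p in patterns) {
    out <- out | startsWith(codes, p)
  }
  out
}
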