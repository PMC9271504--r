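#' Read and write design configurations
#'
#' A design configuration is a small YAML (or JSON — YAML is a superset)
#' document with the keys `p_acceptable`, `p_unacceptable`, `alpha_total`,
#' `power_target`, `horizon_n`, `nonevaluable_rate` and optionally `n_sims`
#' and `seed` for the stochastic operations.
#'
#' @param path File path.
#' @return `read_design_config()` returns a list with elements `design` (an
#'   [sc_design()]), `n_sims` and `seed`.
#' @export
read_design_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  design <- sc_design(
    p_acceptable = cfg$p_acceptable %||% 0.05,
    p_unacceptable = cfg$p_unacceptable %||% 0.10,
    alpha_total = cfg$alpha_total %||% 0.05,
    power_target = cfg$power_target %||% 0.80,
    horizon_n = cfg$horizon_n %||% 225,
    nonevaluable_rate = cfg$nonevaluable_rate %||% 0.10
  )
  list(design = design, n_sims = cfg$n_sims %||% 10000, seed = cfg$seed %||% 1)
}

#' @rdname read_design_config
#' @param design An [sc_design()].
#' @param n_sims,seed Stochastic-operation settings stored alongside.
#' @export
write_design_config <- function(design, path, n_sims = 10000, seed = 1) {
  stopifnot(inherits(design, "sc_design"))
  yaml::write_yaml(c(unclass(design), list(n_sims = n_sims, seed = seed)), path)
  invisible(path)
}

ledger_col_types <- list(
  patients = readr::cols(
    patient_id = readr::col_character(),
    enrollment_date = readr::col_date(),
    prior_followup_years = readr::col_double(),
    status = readr::col_character(),
    censor_date = readr::col_date()
  ),
  visits = readr::cols(
    patient_id = readr::col_character(),
    visit_date = readr::col_date(),
    setting = readr::col_character(),
    markers_ordered = readr::col_character(),
    marker_panel_correct = readr::col_logical(),
    marker_error_detected_by_case_manager = readr::col_logical(),
    abnormal_finding = readr::col_logical(),
    action_lag_days = readr::col_double(),
    ldh_elevated_hemolysis_suspected = readr::col_logical(),
    retest_lag_days = readr::col_double(),
    report_return_lag_days = readr::col_double(),
    cvrm_performed = readr::col_logical(),
    duration_min = readr::col_double()
  ),
  incidents = readr::cols(
    patient_id = readr::col_character(),
    incident_date = readr::col_date(),
    kind = readr::col_character(),
    contact_lag_days = readr::col_double()
  )
)

#' Read and write follow-up ledgers
#'
#' The on-disk ledger is three delimited (CSV) tables named
#' `patients.csv`, `visits.csv` and `incidents.csv` with ISO-8601 dates and a
#' mandatory header row; `markers_ordered` is a `;`-separated panel string.
#' The JSON bundle variant carries all three tables plus provenance metadata
#' in one document.
#'
#' @param dir Directory holding (or to hold) the three CSV files.
#' @return `read_ledger()` returns a validated `sc_ledger`.
#' @export
read_ledger <- function(dir) {
  led <- structure(
    list(
      patients = readr::read_csv(file.path(dir, "patients.csv"),
                                 col_types = ledger_col_types$patients),
      visits = readr::read_csv(file.path(dir, "visits.csv"),
                               col_types = ledger_col_types$visits),
      incidents = readr::read_csv(file.path(dir, "incidents.csv"),
                                  col_types = ledger_col_types$incidents),
      config = NULL
    ),
    class = c("sc_ledger", "list")
  )
  validate_ledger(led)
  led
}

#' @rdname read_ledger
#' @param ledger An `sc_ledger`.
#' @export
write_ledger <- function(ledger, dir) {
  validate_ledger(ledger)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_csv(ledger$patients, file.path(dir, "patients.csv"), na = "")
  readr::write_csv(ledger$visits, file.path(dir, "visits.csv"), na = "")
  readr::write_csv(ledger$incidents, file.path(dir, "incidents.csv"), na = "")
  invisible(dir)
}

#' @rdname read_ledger
#' @param path JSON file path.
#' @param provenance Optional named list stored under `provenance`.
#' @export
write_ledger_json <- function(ledger, path, provenance = list()) {
  validate_ledger(ledger)
  jsonlite::write_json(
    list(provenance = c(list(format = "sharedcare-ledger", version = 1L),
                        provenance),
         patients = ledger$patients,
         visits = ledger$visits,
         incidents = ledger$incidents),
    path, auto_unbox = TRUE, digits = NA, null = "null", na = "null",
    Date = "ISO8601")
  invisible(path)
}

#' @rdname read_ledger
#' @export
read_ledger_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  fix_dates <- function(df, cols) {
    for (cc in intersect(cols, names(df))) df[[cc]] <- as.Date(df[[cc]])
    tibble::as_tibble(df)
  }
  led <- structure(
    list(patients = fix_dates(x$patients, c("enrollment_date", "censor_date")),
         visits = fix_dates(x$visits, "visit_date"),
         incidents = fix_dates(x$incidents, "incident_date"),
         config = NULL),
    class = c("sc_ledger", "list")
  )
  # absent optional columns come back missing when every value was null
  for (tb in c("patients", "visits", "incidents")) {
    tmpl <- switch(tb, patients = patients_cols, visits = visits_cols,
                   incidents = incidents_cols)
    for (cc in setdiff(tmpl, names(led[[tb]]))) led[[tb]][[cc]] <- NA
  }
  validate_ledger(led)
  led
}
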