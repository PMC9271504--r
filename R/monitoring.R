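#' Failure adjudication and sequential monitoring of a follow-up ledger
#'
#' A follow-up ledger is a list of three tables: `patients`, `visits` and
#' `incidents`. The monitoring functions classify every visit against the
#' program's failure rules, reduce each patient to one evaluable Bernoulli
#' outcome (or censoring), and stream the outcomes through the sequential
#' stopping rule.
#'
#' @name monitoring
#' @keywords internal
NULL

CORRECT_PANEL <- c("AFP", "bHCG", "LDH")

patients_cols <- c("patient_id", "enrollment_date", "prior_followup_years",
                   "status", "censor_date")
visits_cols <- c("patient_id", "visit_date", "setting", "markers_ordered",
                 "marker_panel_correct", "marker_error_detected_by_case_manager",
                 "abnormal_finding", "action_lag_days",
                 "ldh_elevated_hemolysis_suspected", "retest_lag_days",
                 "report_return_lag_days", "cvrm_performed", "duration_min")
incidents_cols <- c("patient_id", "incident_date", "kind", "contact_lag_days")

incident_kinds <- c("missed_appointment_uncontactable", "wrong_marker_unnoticed",
                    "late_report", "relapse_detected", "referral")
patient_statuses <- c("active", "completed_2y", "censored", "relapsed")

#' Validate a follow-up ledger
#'
#' Checks that the three ledger tables carry the expected columns, that
#' categorical fields use the documented levels, and that the record-level
#' invariants hold (censor dates present exactly for censored patients,
#' action lags present exactly for abnormal findings, retest lags present
#' exactly for hemolysis-suspect LDH elevations).
#'
#' @param ledger A list with elements `patients`, `visits`, `incidents`.
#' @return The ledger, invisibly, if valid; otherwise a named error of class
#'   `sharedcare_schema`.
#' @export
validate_ledger <- function(ledger) {
  if (!is.list(ledger) ||
      !all(c("patients", "visits", "incidents") %in% names(ledger))) {
    abort_sc("ledger must be a list with patients, visits and incidents tables.",
             "schema")
  }
  need <- function(tbl, cols, what) {
    miss <- setdiff(cols, names(tbl))
    if (length(miss)) {
      abort_sc(sprintf("%s table is missing column(s): %s",
                       what, paste(miss, collapse = ", ")), "schema")
    }
  }
  p <- ledger$patients; v <- ledger$visits; i <- ledger$incidents
  need(p, patients_cols, "patients")
  need(v, visits_cols, "visits")
  need(i, incidents_cols, "incidents")
  if (!all(p$status %in% patient_statuses)) {
    abort_sc("patients$status contains unknown levels.", "schema")
  }
  if (!all(v$setting %in% c("primary_care", "oncology"))) {
    abort_sc("visits$setting must be primary_care or oncology.", "schema")
  }
  if (nrow(i) && !all(i$kind %in% incident_kinds)) {
    abort_sc("incidents$kind contains unknown levels.", "schema")
  }
  if (any((p$status == "censored") != !is.na(p$censor_date))) {
    abort_sc("censor_date must be present iff status is censored.", "schema")
  }
  if (any(xor(v$abnormal_finding, !is.na(v$action_lag_days)))) {
    abort_sc("action_lag_days must be present iff abnormal_finding.", "schema")
  }
  if (any(xor(v$ldh_elevated_hemolysis_suspected, !is.na(v$retest_lag_days)))) {
    abort_sc("retest_lag_days must be present iff hemolysis-suspect LDH.", "schema")
  }
  invisible(ledger)
}

#' Classify a single follow-up visit against the failure rules
#'
#' A visit is a failure when (and only when) one of three things happened:
#' an abnormal finding was not acted on within 14 days; a scheduled
#' appointment was missed and the patient could not be contacted within 14
#' days; or a wrong tumor-marker panel was drawn and the monitoring case
#' manager did not notice. An elevated LDH attributed to hemolysis that is
#' re-tested within 14 days is not a failure, and a late-returned report is
#' a logistics matter, never a failure. "Within 2 weeks" is a lag of at most
#' 14 calendar days, inclusive.
#'
#' @param visit A one-row data frame (or list) with the visit fields.
#' @param linked_incidents Incidents linked to this visit (same patient,
#'   incident on the visit date). Incidents for another patient are rejected.
#' @return A list with `failure` (logical) and `reason` (`NA` or one of
#'   `"late_action"`, `"missed_uncontactable"`, `"wrong_marker"`).
#' @seealso [classify_visits()] for the vectorized table version.
#' @export
classify_visit <- function(visit, linked_incidents = NULL) {
  visit <- as.list(visit)
  if (!is.null(linked_incidents) && nrow(linked_incidents) > 0 &&
      !all(linked_incidents$patient_id == visit$patient_id)) {
    abort_sc("linked incident belongs to a different patient.", "bad_linkage")
  }
  reason <- NA_character_
  if (isTRUE(visit$abnormal_finding) &&
      !is.na(visit$action_lag_days) && visit$action_lag_days > 14) {
    reason <- "late_action"
  } else if (!is.null(linked_incidents) && nrow(linked_incidents) > 0 &&
             any(linked_incidents$kind == "missed_appointment_uncontactable" &
                 !is.na(linked_incidents$contact_lag_days) &
                 linked_incidents$contact_lag_days > 14)) {
    reason <- "missed_uncontactable"
  } else if (identical(visit$marker_panel_correct, FALSE) &&
             identical(visit$marker_error_detected_by_case_manager, FALSE)) {
    reason <- "wrong_marker"
  }
  list(failure = !is.na(reason), reason = reason)
}

#' Classify every visit in a ledger
#'
#' Vectorized [classify_visit()]: incidents are linked to a visit when they
#' concern the same patient and fall on the visit date.
#'
#' @param visits Visits table.
#' @param incidents Incidents table (may be empty).
#' @return The visits table with `failure` (logical) and `failure_reason`
#'   columns appended.
#' @export
classify_visits <- function(visits, incidents = NULL) {
  if (is.null(incidents)) {
    incidents <- tibble::tibble(patient_id = character(),
                                incident_date = as.Date(character()),
                                kind = character(),
                                contact_lag_days = double())
  }
  missed <- dplyr::filter(incidents,
                          .data$kind == "missed_appointment_uncontactable",
                          !is.na(.data$contact_lag_days),
                          .data$contact_lag_days > 14)
  out <- dplyr::left_join(
    visits,
    dplyr::distinct(
      dplyr::transmute(missed, patient_id = .data$patient_id,
                       visit_date = .data$incident_date,
                       .missed_fail = TRUE)
    ),
    by = c("patient_id", "visit_date")
  )
  out$.missed_fail <- !is.na(out$.missed_fail)
  late_action <- out$abnormal_finding & !is.na(out$action_lag_days) &
    out$action_lag_days > 14
  wrong_marker <- !out$marker_panel_correct &
    !out$marker_error_detected_by_case_manager
  out$failure_reason <- dplyr::case_when(
    late_action ~ "late_action",
    out$.missed_fail ~ "missed_uncontactable",
    wrong_marker ~ "wrong_marker",
    TRUE ~ NA_character_
  )
  out$failure <- !is.na(out$failure_reason)
  out$.missed_fail <- NULL
  out
}

#' Reduce each patient to one evaluable outcome
#'
#' Applies the per-patient Bernoulli rule: a patient is a *failure* if any of
#' their visits within the 2-year follow-up window classifies as a failure
#' (the outcome is realized at the first failure date); a *success* if they
#' completed 2 years of shared-care follow-up with at least two primary-care
#' visits and no failure (realized at the end of the window); and *censored*
#' otherwise, contributing nothing to the sequential stream. The 2-year
#' window is 730 days from enrollment, inclusive.
#'
#' @param patients,visits,incidents Ledger tables.
#' @return A tibble with one row per patient: `patient_id`, `outcome`
#'   (`"success"`, `"failure"` or `"censored"`), `outcome_date`,
#'   `failure_reason`.
#' @export
patient_outcomes <- function(patients, visits, incidents = NULL) {
  cls <- classify_visits(visits, incidents)
  window_days <- 730
  pc_counts <- cls |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(
      n_pc = sum(.data$setting == "primary_care"),
      .groups = "drop"
    )
  firsts <- cls |>
    dplyr::filter(.data$failure) |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::slice_min(.data$visit_date, n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::select("patient_id",
                  first_failure_date = "visit_date",
                  first_failure_reason = "failure_reason")
  out <- patients |>
    dplyr::left_join(pc_counts, by = "patient_id") |>
    dplyr::left_join(firsts, by = "patient_id") |>
    dplyr::mutate(n_pc = dplyr::coalesce(.data$n_pc, 0L))
  bad <- out$status == "completed_2y" & out$n_pc < 2
  if (any(bad)) {
    abort_sc(sprintf(
      "contradictory status: patient(s) %s marked completed_2y with fewer than two primary-care visits.",
      paste(out$patient_id[bad], collapse = ", ")), "contradictory_status")
  }
  in_window <- !is.na(out$first_failure_date) &
    as.numeric(out$first_failure_date - out$enrollment_date) <= window_days
  out |>
    dplyr::mutate(
      outcome = dplyr::case_when(
        in_window ~ "failure",
        .data$status == "completed_2y" ~ "success",
        TRUE ~ "censored"
      ),
      outcome_date = dplyr::case_when(
        in_window ~ .data$first_failure_date,
        .data$status == "completed_2y" ~ .data$enrollment_date + window_days,
        .data$status == "censored" ~ .data$censor_date,
        TRUE ~ as.Date(NA)
      ),
      failure_reason = dplyr::if_else(in_window, .data$first_failure_reason,
                                      NA_character_)
    ) |>
    dplyr::select("patient_id", "outcome", "outcome_date", "failure_reason")
}

#' Run the sequential stopping rule over a follow-up ledger
#'
#' Derives per-patient evaluable outcomes with [patient_outcomes()], orders
#' them by realization date (ties broken by patient identifier), streams them
#' through [sc_step()] until a boundary is crossed, and reports the verdict.
#' A cohort exhausting its outcomes without a crossing is `"undecided"`,
#' never coerced to a verdict.
#'
#' @param ledger A validated ledger (list of patients/visits/incidents).
#' @param design An [sc_design()].
#' @param boundary An `sc_boundary`; defaults to the uncalibrated Wald
#'   boundaries of `design`.
#' @return An object of class `sc_monitoring`: `final_state`, `verdict`
#'   (`"safe_crossed"`, `"unsafe_crossed"`, `"undecided"`),
#'   `n_failures_total` (failures in the evaluated stream),
#'   `n_failure_visits` (all failing visits in the ledger, the per-visit
#'   view), `failure_reasons`, `n_censored`, `outcomes`.
#' @examples
#' led <- example_cohort_ledger()
#' res <- run_monitoring(led, sc_design(), wald_boundaries())
#' glance(res)
#' @export
run_monitoring <- function(ledger, design = sc_design(),
                           boundary = wald_boundaries(design)) {
  validate_ledger(ledger)
  cls <- classify_visits(ledger$visits, ledger$incidents)
  outs <- patient_outcomes(ledger$patients, ledger$visits, ledger$incidents)
  stream <- outs |>
    dplyr::filter(.data$outcome != "censored") |>
    dplyr::arrange(.data$outcome_date, .data$patient_id)
  state <- sc_state(design)
  evaluated <- character()
  for (k in seq_len(nrow(stream))) {
    state <- sc_step(state, stream$outcome[k], boundary)
    evaluated <- c(evaluated, stream$patient_id[k])
    if (state$status != "continue") break
  }
  verdict <- switch(state$status,
                    safe = "safe_crossed",
                    unsafe = "unsafe_crossed",
                    "undecided")
  structure(
    list(final_state = state,
         verdict = verdict,
         n_failures_total = state$n_failures,
         n_failure_visits = sum(cls$failure),
         failure_reasons = table(cls$failure_reason[cls$failure]),
         n_censored = sum(outs$outcome == "censored"),
         outcomes = outs,
         boundary = boundary,
         evaluated_patients = evaluated),
    class = "sc_monitoring"
  )
}

#' @export
print.sc_monitoring <- function(x, ...) {
  cat("<sc_monitoring>\n")
  cat(sprintf("  verdict: %s after %d evaluable outcomes (%d failures)\n",
              x$verdict, x$final_state$n_evaluable, x$n_failures_total))
  cat(sprintf("  failing visits in ledger: %d; censored patients: %d\n",
              x$n_failure_visits, x$n_censored))
  invisible(x)
}

#' @export
tidy.sc_monitoring <- function(x, ...) {
  trajectory_series(x, x$boundary)
}

#' @export
glance.sc_monitoring <- function(x, ...) {
  tibble::tibble(
    verdict = x$verdict,
    n_evaluable = x$final_state$n_evaluable,
    n_failures = x$n_failures_total,
    n_failure_visits = x$n_failure_visits,
    n_censored = x$n_censored,
    cum_llr = x$final_state$cum_llr,
    log_lower = x$boundary$log_lower,
    log_upper = x$boundary$log_upper
  )
}
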