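# Independent oracles and small fixture builders.

# Exact decision probabilities by enumeration of all 2^h weighted outcome
# sequences (1 = failure). Written independently of the package's stepping
# and simulation code.
oracle_enum_oc <- function(h, p, log_lower, log_upper, llr_fail, llr_succ) {
  grid <- as.matrix(expand.grid(rep(list(c(0L, 1L)), h)))
  weights <- apply(grid, 1, function(x) prod(ifelse(x == 1L, p, 1 - p)))
  verdict <- apply(grid, 1, function(x) {
    cum <- cumsum(ifelse(x == 1L, llr_fail, llr_succ))
    iu <- which(cum >= log_upper)[1]
    il <- which(cum <= log_lower)[1]
    if (!is.na(iu) && (is.na(il) || iu <= il)) {
      "unsafe"
    } else if (!is.na(il)) {
      "safe"
    } else {
      "undecided"
    }
  })
  c(safe = sum(weights[verdict == "safe"]),
    unsafe = sum(weights[verdict == "unsafe"]),
    undecided = sum(weights[verdict == "undecided"]))
}

# SCORE oracle values, frozen from an independent evaluation of the
# published low-risk Weibull coefficients (CHD + non-CHD, 10-year
# conditional risk, total-cholesterol variant).
score_oracle_values <- tibble::tribble(
  ~age, ~sex,     ~sbp, ~chol, ~smoker, ~risk_pct,
  35,   "male",   120,  4.0,   FALSE,   0.07217624,
  35,   "male",   120,  4.0,   TRUE,    0.14401500,
  53.2, "male",   125,  5.0,   FALSE,   1.13542200,
  65,   "male",   170,  7.5,   TRUE,    22.31445000,
  65,   "female", 170,  7.5,   TRUE,    11.45382000
)

make_patient <- function(patient_id = "P1",
                         enrollment_date = as.Date("2013-01-01"),
                         prior_followup_years = 1,
                         status = "completed_2y",
                         censor_date = as.Date(NA)) {
  tibble::tibble(patient_id = patient_id, enrollment_date = enrollment_date,
                 prior_followup_years = prior_followup_years, status = status,
                 censor_date = censor_date)
}

make_visit <- function(patient_id = "P1",
                       visit_date = as.Date("2013-04-01"),
                       setting = "primary_care",
                       markers_ordered = "AFP;bHCG;LDH",
                       marker_panel_correct = TRUE,
                       marker_error_detected_by_case_manager = NA,
                       abnormal_finding = FALSE,
                       action_lag_days = NA_real_,
                       ldh_elevated_hemolysis_suspected = FALSE,
                       retest_lag_days = NA_real_,
                       report_return_lag_days = 5,
                       cvrm_performed = TRUE,
                       duration_min = 20) {
  tibble::tibble(patient_id = patient_id, visit_date = visit_date,
                 setting = setting, markers_ordered = markers_ordered,
                 marker_panel_correct = marker_panel_correct,
                 marker_error_detected_by_case_manager =
                   marker_error_detected_by_case_manager,
                 abnormal_finding = abnormal_finding,
                 action_lag_days = action_lag_days,
                 ldh_elevated_hemolysis_suspected =
                   ldh_elevated_hemolysis_suspected,
                 retest_lag_days = retest_lag_days,
                 report_return_lag_days = report_return_lag_days,
                 cvrm_performed = cvrm_performed, duration_min = duration_min)
}

empty_incidents <- function() {
  tibble::tibble(patient_id = character(),
                 incident_date = as.Date(character()),
                 kind = character(), contact_lag_days = double())
}

make_ledger <- function(patients, visits, incidents = empty_incidents()) {
  structure(list(patients = patients, visits = visits, incidents = incidents,
                 config = NULL),
            class = c("sc_ledger", "list"))
}

# a clean completer: enrollment, three timely primary-care visits
completer <- function(id, enroll = as.Date("2013-01-01")) {
  list(
    patient = make_patient(id, enrollment_date = enroll),
    visits = dplyr::bind_rows(
      make_visit(id, enroll + 91),
      make_visit(id, enroll + 274),
      make_visit(id, enroll + 457)
    )
  )
}

# ledger of n clean completers enrolled one week apart
completer_ledger <- function(n, start = as.Date("2013-01-01")) {
  parts <- lapply(seq_len(n), function(i) {
    completer(sprintf("C%03d", i), start + 7 * (i - 1))
  })
  make_ledger(dplyr::bind_rows(lapply(parts, `[[`, "patient")),
              dplyr::bind_rows(lapply(parts, `[[`, "visits")))
}
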