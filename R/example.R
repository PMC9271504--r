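#' Worked-example follow-up ledger (synthetic reconstruction)
#'
#' A fully deterministic synthetic ledger that reproduces the headline counts
#' of a shared-care testicular-cancer follow-up program: 162 enrolled
#' patients of whom 113 completed two years with at least two primary-care
#' visits, 30 stopped early and 6 relapsed (timely detected at oncology
#' visits); 364 primary-care visits in total, 26 of them with a
#' hemolysis-suspect LDH elevation re-tested within two weeks, 81 with the
#' report returned after more than 21 days and 73 within one day, one benign
#' referral after an abnormal physical exam; and exactly four failed visits —
#' three missed appointments where the patient could not be contacted within
#' two weeks and one wrong tumor-marker panel that the monitoring case
#' manager did not notice. 140 patients have at least one primary-care visit
#' with cardiovascular risk management.
#'
#' The calendar ordering of the four failures is fixed (spread over
#' 2015-2017, interleaved among the completers' outcomes); the stopping-rule
#' verdict on this ledger is a safe crossing. A hypothetical ordering with
#' all four failures as the very first evaluable outcomes would instead touch
#' the unsafe threshold exactly, so the verdict is reported for the
#' documented ordering, not assumed order-free.
#'
#' @return An `sc_ledger` (patients, visits, incidents tibbles).
#' @examples
#' led <- example_cohort_ledger()
#' cohort_flow(led$patients)
#' @export
example_cohort_ledger <- function() {
  start <- as.Date("2012-10-01")
  end <- as.Date("2017-01-31")
  span <- as.numeric(end - start)

  # roles: 109 completers without failure + 4 failure completers = 113;
  # 30 censored, 6 relapsed, 13 active at data cut
  fail_visit_dates <- as.Date(c("2015-03-10", "2015-11-05",
                                "2016-06-20", "2017-02-01"))
  fail_kinds <- c("missed_uncontactable", "missed_uncontactable",
                  "missed_uncontactable", "wrong_marker")
  roles <- c(rep("completer", 109), rep("failure", 4), rep("censored", 30),
             rep("relapsed", 6), rep("active", 13))
  n <- length(roles)
  ids <- sprintf("S%03d", seq_len(n))

  enroll <- start + round((seq_len(n) - 1) * span / (n - 1))
  # failures occur at the month-9 primary-care visit (day 274)
  fail_idx <- which(roles == "failure")
  enroll[fail_idx] <- fail_visit_dates - 274

  # primary-care visit plan: 111 completers with 3 visits, 2 with 2 visits;
  # 12 censored, all 6 relapsed and 9 active patients with 1 visit each
  # (364 primary-care visits; 140 patients with at least one)
  comp_idx <- which(roles %in% c("completer", "failure"))
  pc_months <- vector("list", n)
  pc_months[comp_idx] <- rep(list(c(3, 9, 15)), length(comp_idx))
  pc_months[comp_idx[1:2]] <- rep(list(c(3, 9)), 2)
  cens_idx <- which(roles == "censored")
  rel_idx <- which(roles == "relapsed")
  act_idx <- which(roles == "active")
  one_visit <- c(cens_idx[1:12], rel_idx, act_idx[1:9])
  pc_months[one_visit] <- rep(list(3), length(one_visit))

  status <- dplyr::case_when(roles %in% c("completer", "failure") ~ "completed_2y",
                             roles == "censored" ~ "censored",
                             roles == "relapsed" ~ "relapsed",
                             TRUE ~ "active")
  censor_date <- dplyr::if_else(
    status == "censored",
    enroll + ifelse(seq_len(n) %in% one_visit, 8 * 30, 2 * 30),
    as.Date(NA))
  patients <- tibble::tibble(
    patient_id = ids,
    enrollment_date = enroll,
    prior_followup_years = round(0.6 + 10.9 * ((seq_len(n) - 1) %% 23) / 22, 1),
    status = status,
    censor_date = censor_date
  )

  blank_visit <- function(pid, date, setting) {
    tibble::tibble(
      patient_id = pid, visit_date = date, setting = setting,
      markers_ordered = "AFP;bHCG;LDH", marker_panel_correct = TRUE,
      marker_error_detected_by_case_manager = NA,
      abnormal_finding = FALSE, action_lag_days = NA_real_,
      ldh_elevated_hemolysis_suspected = FALSE, retest_lag_days = NA_real_,
      report_return_lag_days = NA_real_, cvrm_performed = FALSE,
      duration_min = 20
    )
  }

  pc <- dplyr::bind_rows(lapply(seq_len(n), function(i) {
    if (is.null(pc_months[[i]])) return(NULL)
    v <- blank_visit(ids[i], enroll[i] + round(pc_months[[i]] * 30.44),
                     "primary_care")
    v$cvrm_performed <- TRUE
    v
  }))
  stopifnot(nrow(pc) == 364)

  # logistics attributes, spread deterministically across the 364 visits
  k <- seq_len(nrow(pc))
  pc$report_return_lag_days <- 10
  within1 <- utils::head(which(k %% 4 == 0), 73)           # 73 within a day
  pc$report_return_lag_days[within1] <- 1
  rest <- setdiff(k, within1)
  late <- rest[round(seq(1, length(rest), length.out = 81))]
  pc$report_return_lag_days[late] <- 25                    # 81 later than 21 d
  hemo <- which(k %% 14 == 2)[1:26]
  pc$ldh_elevated_hemolysis_suspected[hemo] <- TRUE
  pc$retest_lag_days[hemo] <- 7
  referral_row <- which(k %% 100 == 50)[1]
  pc$abnormal_finding[referral_row] <- TRUE
  pc$action_lag_days[referral_row] <- 3

  # the four failure mechanisms at the month-9 visits of the failure patients
  incidents <- tibble::tibble(patient_id = character(),
                              incident_date = as.Date(character()),
                              kind = character(), contact_lag_days = double())
  for (j in seq_along(fail_idx)) {
    i <- fail_idx[j]
    row <- which(pc$patient_id == ids[i] & pc$visit_date == fail_visit_dates[j])
    if (fail_kinds[j] == "wrong_marker") {
      pc$markers_ordered[row] <- "AFP;LDH"
      pc$marker_panel_correct[row] <- FALSE
      pc$marker_error_detected_by_case_manager[row] <- FALSE
      incidents <- dplyr::bind_rows(incidents, tibble::tibble(
        patient_id = ids[i], incident_date = fail_visit_dates[j],
        kind = "wrong_marker_unnoticed", contact_lag_days = NA_real_))
    } else {
      incidents <- dplyr::bind_rows(incidents, tibble::tibble(
        patient_id = ids[i], incident_date = fail_visit_dates[j],
        kind = "missed_appointment_uncontactable",
        contact_lag_days = c(16, 18, 21)[j]))
    }
  }
  incidents <- dplyr::bind_rows(incidents, tibble::tibble(
    patient_id = pc$patient_id[referral_row],
    incident_date = pc$visit_date[referral_row],
    kind = "referral", contact_lag_days = NA_real_))

  onc <- dplyr::bind_rows(lapply(seq_len(n), function(i) {
    months <- if (roles[i] %in% c("completer", "failure")) {
      c(6, 12, 24)
    } else if (roles[i] == "relapsed") {
      12
    } else {
      NULL
    }
    if (is.null(months)) return(NULL)
    blank_visit(ids[i], enroll[i] + round(months * 30.44), "oncology")
  }))
  for (i in rel_idx) {
    row <- which(onc$patient_id == ids[i])
    onc$abnormal_finding[row] <- TRUE
    onc$action_lag_days[row] <- 5
    incidents <- dplyr::bind_rows(incidents, tibble::tibble(
      patient_id = ids[i], incident_date = onc$visit_date[row],
      kind = "relapse_detected", contact_lag_days = NA_real_))
  }

  visits <- dplyr::arrange(dplyr::bind_rows(pc, onc),
                           .data$visit_date, .data$patient_id)
  structure(list(patients = patients, visits = visits, incidents = incidents,
                 config = NULL),
            class = c("sc_ledger", "list"))
}

#' Worked-example CVRM measurements (synthetic reconstruction)
#'
#' 140 assessment rows mirroring the program's printed risk-category
#' distribution under this package's SCORE implementation: 75 low-risk
#' profiles, 18 mid, 7 high and 40 with a missing cholesterol (risk not
#' reported). (The printed category rows sum to one more than the stated
#' denominator of 140; the low-risk count is reduced by one here.) Metabolic
#' syndrome inputs are complete for 105 rows, 27 of which meet three
#' criteria, matching the reported 27/105 prevalence.
#'
#' @return A tibble of 140 measurement rows.
#' @examples
#' a <- assess_cvrm(example_cvrm_measurements())
#' table(a$risk_category)
#' @export
example_cvrm_measurements <- function() {
  base <- tibble::tibble(
    age_years = 38.2, sex = "male", sbp_mmHg = 125, dbp_mmHg = 78,
    waist_cm = 92, weight_kg = 84.5, bmi = 25.5, hdl_mmol_l = 1.30,
    total_chol_mmol_l = 5.0, triglycerides_mmol_l = 1.30,
    glucose_mmol_l = 5.3, hba1c = 5.4, smoker = FALSE,
    on_antihypertensive = FALSE, on_statin = FALSE, on_antidiabetic = FALSE
  )
  m <- base[rep(1, 140), ]
  mid <- 76:93          # 18 mid-risk profiles
  high <- 94:100        # 7 high-risk profiles
  missing_chol <- 101:140
  m$age_years[mid] <- 48; m$smoker[mid] <- TRUE
  m$sbp_mmHg[mid] <- 155; m$total_chol_mmol_l[mid] <- 6.5
  m$age_years[high] <- 50; m$smoker[high] <- TRUE
  m$sbp_mmHg[high] <- 170; m$total_chol_mmol_l[high] <- 7.5
  m$total_chol_mmol_l[missing_chol] <- NA_real_
  # metabolic syndrome: 27 of the first 105 rows meet three criteria,
  # the remaining 35 rows are indeterminate (waist not measured)
  mets <- 1:27
  m$waist_cm[mets] <- 110
  m$triglycerides_mmol_l[mets] <- 2.0
  m$hdl_mmol_l[mets] <- 0.9
  m$waist_cm[106:140] <- NA_real_
  m
}
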