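test_that("visit classification follows the two-week and wrong-marker rules", {
  # wrong marker ordered, case manager did not notice -> failure
  v <- make_visit(markers_ordered = "AFP;LDH", marker_panel_correct = FALSE,
                  marker_error_detected_by_case_manager = FALSE)
  expect_identical(classify_visit(v),
                   list(failure = TRUE, reason = "wrong_marker"))
  # ... but a caught wrong marker is not a failure
  v$marker_error_detected_by_case_manager <- TRUE
  expect_false(classify_visit(v)$failure)

  # hemolysis-suspect LDH re-tested at 10 days -> not a failure
  v <- make_visit(ldh_elevated_hemolysis_suspected = TRUE, retest_lag_days = 10)
  expect_false(classify_visit(v)$failure)

  # abnormal exam, referral after 3 days -> not a failure
  v <- make_visit(abnormal_finding = TRUE, action_lag_days = 3)
  expect_false(classify_visit(v)$failure)

  # abnormal finding acted on at day 15: one past the inclusive 14-day bound
  v <- make_visit(abnormal_finding = TRUE, action_lag_days = 15)
  expect_identical(classify_visit(v),
                   list(failure = TRUE, reason = "late_action"))
  v$action_lag_days <- 14
  expect_false(classify_visit(v)$failure)

  # uncontactable missed appointment beyond two weeks -> failure
  inc <- tibble::tibble(patient_id = "P1",
                        incident_date = as.Date("2013-04-01"),
                        kind = "missed_appointment_uncontactable",
                        contact_lag_days = 20)
  expect_identical(classify_visit(make_visit(), inc),
                   list(failure = TRUE, reason = "missed_uncontactable"))
  inc$contact_lag_days <- 14
  expect_false(classify_visit(make_visit(), inc)$failure)

  # incident for another patient is malformed linkage
  inc$patient_id <- "P2"
  expect_error(classify_visit(make_visit(), inc),
               class = "sharedcare_bad_linkage")
})

test_that("vectorized classification matches the single-visit rule", {
  visits <- dplyr::bind_rows(
    make_visit("P1", as.Date("2013-04-01")),
    make_visit("P1", as.Date("2013-10-01"), abnormal_finding = TRUE,
               action_lag_days = 20),
    make_visit("P2", as.Date("2013-04-01"), marker_panel_correct = FALSE,
               marker_error_detected_by_case_manager = FALSE),
    make_visit("P3", as.Date("2013-04-01"))
  )
  inc <- tibble::tibble(patient_id = "P3", incident_date = as.Date("2013-04-01"),
                        kind = "missed_appointment_uncontactable",
                        contact_lag_days = 16)
  cls <- classify_visits(visits, inc)
  expect_identical(cls$failure, c(FALSE, TRUE, TRUE, TRUE))
  expect_identical(cls$failure_reason,
                   c(NA, "late_action", "wrong_marker", "missed_uncontactable"))
})

test_that("patients reduce to success, failure-at-first-event or censoring", {
  enroll <- as.Date("2013-01-01")
  # clean completer -> success at end of the 2-year window
  c1 <- completer("P1", enroll)
  out <- patient_outcomes(c1$patient, c1$visits)
  expect_identical(out$outcome, "success")
  expect_identical(out$outcome_date, enroll + 730)

  # stopped at month 8 by preference for hospital care -> censored
  p2 <- make_patient("P2", enroll, status = "censored",
                     censor_date = enroll + 240)
  v2 <- make_visit("P2", enroll + 91)
  out2 <- patient_outcomes(p2, v2)
  expect_identical(out2$outcome, "censored")

  # wrong-marker failure at month 6 then dropout -> failure at the first event
  p3 <- make_patient("P3", enroll, status = "censored",
                     censor_date = enroll + 300)
  v3 <- dplyr::bind_rows(
    make_visit("P3", enroll + 91),
    make_visit("P3", enroll + 183, marker_panel_correct = FALSE,
               marker_error_detected_by_case_manager = FALSE)
  )
  out3 <- patient_outcomes(p3, v3)
  expect_identical(out3$outcome, "failure")
  expect_identical(out3$outcome_date, enroll + 183)
  expect_identical(out3$failure_reason, "wrong_marker")

  # completed_2y without two primary-care visits is contradictory
  p4 <- make_patient("P4", enroll)
  v4 <- make_visit("P4", enroll + 91)
  expect_error(patient_outcomes(p4, v4),
               class = "sharedcare_contradictory_status")
})

test_that("monitoring streams outcomes to the documented verdicts", {
  d <- sc_design()
  b <- wald_boundaries(d)

  # four consecutive failures as the first outcomes -> unsafe crossing
  enroll <- as.Date("2013-01-01")
  parts <- lapply(1:4, function(i) {
    id <- sprintf("F%d", i)
    list(patient = make_patient(id, enroll + i, status = "censored",
                                censor_date = enroll + 400 + i),
         visits = make_visit(id, enroll + 91 + i, marker_panel_correct = FALSE,
                             marker_error_detected_by_case_manager = FALSE))
  })
  led <- make_ledger(dplyr::bind_rows(lapply(parts, `[[`, "patient")),
                     dplyr::bind_rows(lapply(parts, `[[`, "visits")))
  res <- run_monitoring(led, d, b)
  expect_identical(res$verdict, "unsafe_crossed")
  expect_identical(res$n_failures_total, 4L)

  # 29 clean completers -> safe crossing exactly at the 29th outcome
  led29 <- completer_ledger(35)
  res29 <- run_monitoring(led29, d, b)
  expect_identical(res29$verdict, "safe_crossed")
  expect_identical(res29$final_state$n_evaluable, 29L)

  # empty ledger -> undecided with an empty trajectory
  led0 <- make_ledger(make_patient()[0, ], make_visit()[0, ])
  res0 <- run_monitoring(led0, d, b)
  expect_identical(res0$verdict, "undecided")
  expect_identical(nrow(res0$final_state$trajectory), 0L)
})

test_that("censored patients and report lags never affect the verdict", {
  led <- example_cohort_ledger()
  d <- sc_design()
  b <- wald_boundaries(d)
  base <- run_monitoring(led, d, b)

  # perturb censoring dates (permuting censored patients in calendar time)
  led2 <- led
  idx <- which(led2$patients$status == "censored")
  led2$patients$censor_date[idx] <-
    rev(led2$patients$censor_date[idx]) + rep(c(5, -5), length.out = length(idx))
  res2 <- run_monitoring(led2, d, b)
  expect_identical(res2$verdict, base$verdict)
  expect_identical(res2$n_failures_total, base$n_failures_total)

  # report-return lags are logistics, not failures
  led3 <- led
  led3$visits$report_return_lag_days <-
    dplyr::if_else(is.na(led3$visits$report_return_lag_days), NA_real_, 60)
  res3 <- run_monitoring(led3, d, b)
  expect_identical(res3$n_failures_total, base$n_failures_total)
  expect_identical(res3$verdict, base$verdict)
})

test_that("evaluable failure fraction recovers the generating probability", {
  cfg <- cohort_config(n_patients = 1000, p_failure = 0.05, seed = 404)
  led <- generate_cohort(cfg)
  outs <- patient_outcomes(led$patients, led$visits, led$incidents)
  ev <- outs[outs$outcome != "censored", ]
  phat <- mean(ev$outcome == "failure")
  se <- sqrt(cfg$p_failure * (1 - cfg$p_failure) / nrow(ev))
  expect_lt(abs(phat - cfg$p_failure), 3 * se)
})
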