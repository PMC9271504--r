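test_that("generation is byte-identical under the same seed", {
  cfg <- cohort_config(n_patients = 40, seed = 77)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$patients, b$patients)
  expect_identical(a$visits, b$visits)
  expect_identical(a$incidents, b$incidents)
  qa <- generate_questionnaires(cfg, a$patients)
  qb <- generate_questionnaires(cfg, b$patients)
  expect_identical(qa, qb)
  ma <- generate_measurements(cfg, 50)
  mb <- generate_measurements(cfg, 50)
  expect_identical(ma, mb)
})

test_that("generated ledgers pass schema validation and feed the monitor", {
  cfg <- cohort_config(n_patients = 50, seed = 15)
  led <- generate_cohort(cfg)
  expect_silent(validate_ledger(led))
  # a failure-free, dropout-free cohort is all successes and crosses safe
  cfg0 <- cohort_config(n_patients = 40, p_failure = 0, p_dropout = 0,
                        relapse_rate = 0, seed = 16)
  led0 <- generate_cohort(cfg0)
  outs <- patient_outcomes(led0$patients, led0$visits, led0$incidents)
  expect_true(all(outs$outcome == "success"))
  res <- run_monitoring(led0, sc_design(), wald_boundaries())
  expect_identical(res$verdict, "safe_crossed")
  expect_identical(res$final_state$n_evaluable, 29L)
})

test_that("an infeasible visit schedule is rejected", {
  expect_error(cohort_config(followup_horizon_years = 0.25),
               class = "sharedcare_invalid_config")
})

test_that("per-visit incident rates match their configured targets", {
  cfg <- cohort_config(n_patients = 2600, seed = 99)
  led <- generate_cohort(cfg)
  pc <- led$visits[led$visits$setting == "primary_care", ]
  n <- nrow(pc)
  expect_gt(n, 9000)
  frac_hemo <- mean(pc$ldh_elevated_hemolysis_suspected)
  se_hemo <- sqrt(cfg$rate_hemolysis * (1 - cfg$rate_hemolysis) / n)
  expect_lt(abs(frac_hemo - cfg$rate_hemolysis), 3 * se_hemo)
  frac_late <- mean(pc$report_return_lag_days > 21)
  se_late <- sqrt(cfg$rate_late_report * (1 - cfg$rate_late_report) / n)
  expect_lt(abs(frac_late - cfg$rate_late_report), 3 * se_late)
  frac_day <- mean(pc$report_return_lag_days <= 1)
  se_day <- sqrt(cfg$rate_same_day_report * (1 - cfg$rate_same_day_report) / n)
  expect_lt(abs(frac_day - cfg$rate_same_day_report), 3 * se_day)
})

test_that("measurement distributions hit the configured medians and rates", {
  cfg <- cohort_config(seed = 31)
  m <- generate_measurements(cfg, 10000)
  expect_gt(stats::median(m$sbp_mmHg), 123)
  expect_lt(stats::median(m$sbp_mmHg), 127)
  targets <- cfg$measurement_params
  for (v in c("dbp_mmHg", "waist_cm", "hdl_mmol_l", "triglycerides_mmol_l",
              "glucose_mmol_l")) {
    med_target <- targets$median[targets$variable == v]
    expect_equal(stats::median(m[[v]]), med_target, tolerance = 0.03)
  }
  se_smoke <- sqrt(cfg$p_smoker * (1 - cfg$p_smoker) / 10000)
  expect_lt(abs(mean(m$smoker) - cfg$p_smoker), 3 * se_smoke)
  # single row is schema-valid and physiologically plausible
  one <- generate_measurements(cfg, 1)
  expect_identical(nrow(one), 1L)
  expect_true(one$sbp_mmHg > one$dbp_mmHg)
  expect_true(all(one$age_years >= 18, one$hdl_mmol_l > 0, one$bmi > 10))
})

test_that("questionnaire generation hits the anxiety mean and flag targets", {
  cfg <- cohort_config(n_patients = 5000, seed = 62)
  pats <- tibble::tibble(patient_id = sprintf("P%04d", 1:5000))
  q <- generate_questionnaires(cfg, pats)
  scored <- hads_a_score(q$hads)
  base <- scored[scored$administration_label == "baseline", ]
  expect_gt(mean(base$hads_a), 3.0)
  expect_lt(mean(base$hads_a), 3.4)
  se_flag <- sqrt(cfg$hads_flag * (1 - cfg$hads_flag) / nrow(base))
  expect_lt(abs(mean(base$anxiety_flag) - cfg$hads_flag), 3 * se_flag)
  # zero shift: follow-up reproduces the baseline mean
  fu <- scored[scored$administration_label == "followup", ]
  expect_lt(abs(mean(fu$hads_a) - mean(base$hads_a)), 0.15)
  # +3 shift moves the follow-up mean by about 3 points
  cfg3 <- cohort_config(n_patients = 5000, hads_shift = 3, seed = 62)
  q3 <- generate_questionnaires(cfg3, pats)
  s3 <- hads_a_score(q3$hads)
  d3 <- mean(s3$hads_a[s3$administration_label == "followup"]) -
    mean(s3$hads_a[s3$administration_label == "baseline"])
  expect_lt(abs(d3 - 3), 0.2)
  # RAND-36 responses score inside their bounds
  rs <- rand36_subscales(q$rand36[1:500, ])
  vals <- as.matrix(rs[, !(names(rs) %in% c("patient_id", "administration_label"))])
  expect_true(all(vals >= 0 & vals <= 100))
})

test_that("the evaluable failure rate recovers p_failure across settings", {
  for (p in c(0.02, 0.10)) {
    cfg <- cohort_config(n_patients = 1000, p_failure = p, seed = 1000 + p * 100)
    led <- generate_cohort(cfg)
    outs <- patient_outcomes(led$patients, led$visits, led$incidents)
    ev <- outs[outs$outcome != "censored", ]
    se <- sqrt(p * (1 - p) / nrow(ev))
    expect_lt(abs(mean(ev$outcome == "failure") - p), 3 * se)
  }
})
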