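test_that("the survivor age adjustment adds 15 years", {
  expect_equal(adjusted_age(38.2), 53.2)
  expect_equal(adjusted_age(20.5), 35.5)
  expect_equal(adjusted_age(18), 33)
  expect_error(adjusted_age(17), class = "sharedcare_invalid_age")
})

test_that("SCORE risks match an independent evaluation of the published equations", {
  for (i in seq_len(nrow(score_oracle_values))) {
    v <- score_oracle_values[i, ]
    expect_equal(score_risk(v$age, v$sex, v$sbp, v$chol, v$smoker),
                 v$risk_pct, tolerance = 1e-6)
  }
  # identical inputs evaluated twice give identical output
  expect_identical(score_risk(53.2, "male", 125, 5.0, FALSE),
                   score_risk(53.2, "male", 125, 5.0, FALSE))
  # risk-factor-free young profile stays below 1%
  expect_lt(score_risk(35, "male", 120, 4.0, FALSE), 1)
})

test_that("SCORE risk is monotone in each risk factor over the validity range", {
  ages <- seq(40, 65, by = 5)
  sbps <- seq(100, 180, by = 20)
  chols <- seq(3, 8, by = 1)
  # smoking increases risk everywhere on the grid
  grid <- expand.grid(age = ages, sbp = sbps, chol = chols)
  r_ns <- score_risk(grid$age, "male", grid$sbp, grid$chol, FALSE)
  r_sm <- score_risk(grid$age, "male", grid$sbp, grid$chol, TRUE)
  expect_true(all(r_sm > r_ns))
  # non-decreasing along each axis
  expect_true(all(diff(score_risk(ages, "male", 140, 5, FALSE)) > 0))
  expect_true(all(diff(score_risk(55, "male", sbps, 5, FALSE)) > 0))
  expect_true(all(diff(score_risk(55, "male", 140, chols, FALSE)) > 0))
})

test_that("inputs outside the SCORE validity window are clipped with a warning", {
  expect_warning(r_hi <- score_risk(80, "male", 140, 5, FALSE),
                 "clipped")
  expect_equal(r_hi, score_risk(65, "male", 140, 5, FALSE))
})

test_that("risk categories partition the non-negative axis left-closed", {
  expect_identical(risk_category(c(0, 5, 9.999)), rep("low_0_10", 3))
  expect_identical(risk_category(c(10, 19.999)), rep("mid_10_20", 2))
  expect_identical(risk_category(c(20, 45)), rep("high_ge_20", 2))
  expect_identical(risk_category(NA_real_), "not_reported")
  expect_error(risk_category(-1), class = "sharedcare_invalid_measurement")
  # no gaps or overlaps on a random grid
  set.seed(5)
  x <- stats::runif(200, 0, 40)
  cat <- risk_category(x)
  expect_true(all((x < 10) == (cat == "low_0_10")))
  expect_true(all((x >= 10 & x < 20) == (cat == "mid_10_20")))
  expect_true(all((x >= 20) == (cat == "high_ge_20")))
})

test_that("metabolic syndrome requires three of five ATP-III criteria", {
  all5 <- data.frame(waist_cm = 110, triglycerides_mmol_l = 2.0,
                     hdl_mmol_l = 0.9, sbp_mmHg = 135, dbp_mmHg = 88,
                     glucose_mmol_l = 6.0, on_antihypertensive = FALSE,
                     on_antidiabetic = FALSE)
  expect_true(metabolic_syndrome(all5))
  two <- all5
  two$hdl_mmol_l <- 1.3; two$sbp_mmHg <- 120; two$dbp_mmHg <- 78
  two$glucose_mmol_l <- 5.0
  expect_false(metabolic_syndrome(two))
  # medication counts toward the pressure and glucose criteria
  two$on_antihypertensive <- TRUE
  expect_true(metabolic_syndrome(two))
  # reported median profile meets no criterion
  med <- data.frame(waist_cm = 92, triglycerides_mmol_l = 1.30,
                    hdl_mmol_l = 1.30, sbp_mmHg = 125, dbp_mmHg = 78,
                    glucose_mmol_l = 5.3, on_antihypertensive = FALSE,
                    on_antidiabetic = FALSE)
  expect_false(metabolic_syndrome(med))
  # indeterminate when a criterion input is missing
  med$waist_cm <- NA_real_
  expect_true(is.na(metabolic_syndrome(med)))
})

test_that("advice rules cover smoking, weight, exercise and medication", {
  base <- tibble::tibble(
    age_years = 35, sex = "male", sbp_mmHg = 120, dbp_mmHg = 75,
    waist_cm = 88, weight_kg = 75, bmi = 23, hdl_mmol_l = 1.4,
    total_chol_mmol_l = 4.0, triglycerides_mmol_l = 1.0,
    glucose_mmol_l = 5.0, hba1c = 5.2, smoker = FALSE,
    on_antihypertensive = FALSE, on_statin = FALSE, on_antidiabetic = FALSE
  )
  # risk-factor-free profile: no advice at all
  a0 <- assess_cvrm(base)
  expect_identical(a0$advice[[1]], character())
  # smoker with otherwise normal metabolics: stop smoking only
  sm <- base; sm$smoker <- TRUE
  expect_identical(assess_cvrm(sm)$advice[[1]], "stop_smoking")
  # high-risk untreated profile includes a medication recommendation
  hi <- base
  hi$age_years <- 50; hi$smoker <- TRUE; hi$sbp_mmHg <- 170
  hi$total_chol_mmol_l <- 7.5
  adv <- assess_cvrm(hi)$advice[[1]]
  expect_true("new_medication" %in% adv)
  expect_true("more_exercise" %in% adv)
  # ... but not when already on both corresponding therapies
  hi$on_antihypertensive <- TRUE
  expect_false("new_medication" %in% assess_cvrm(hi)$advice[[1]])
})

test_that("missing SCORE inputs surface as not_reported assessments", {
  m <- example_cvrm_measurements()
  a <- assess_cvrm(m)
  expect_identical(sum(a$risk_category == "not_reported"), 40L)
  expect_true(all(is.na(a$score_risk_pct[a$risk_category == "not_reported"])))
  expect_identical(sum(!is.na(a$metabolic_syndrome)), 105L)
  expect_identical(sum(a$metabolic_syndrome, na.rm = TRUE), 27L)
})
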