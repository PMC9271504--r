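#' Survivor age adjustment for cardiovascular risk estimation
#'
#' Testicular cancer survivors treated with platinum-based chemotherapy carry
#' an elevated cardiovascular risk; the program therefore evaluates the SCORE
#' model at the patient's actual age plus 15 years.
#'
#' @param age_years Numeric vector of ages (years), each at least 18.
#' @return `age_years + 15`.
#' @examples
#' adjusted_age(38.2)
#' @export
adjusted_age <- function(age_years) {
  if (any(!is.finite(age_years) | age_years < 18)) {
    abort_sc("ages must be finite and at least 18 years.", "invalid_age")
  }
  age_years + 15
}

# SCORE low-risk-region Weibull coefficients (CHD and non-CHD CVD), and the
# validity window within which inputs are evaluated (clipped with a warning
# outside it)
score_coefs <- list(
  male = list(chd = c(alpha = -22.1, p = 4.71),
              nonchd = c(alpha = -26.7, p = 5.64)),
  female = list(chd = c(alpha = -29.8, p = 6.36),
                nonchd = c(alpha = -31.0, p = 6.62)),
  beta = list(chd = c(chol = 0.24, sbp = 0.018, smoker = 0.71),
              nonchd = c(chol = 0.02, sbp = 0.022, smoker = 0.63))
)
score_limits <- list(age = c(20, 65), sbp = c(100, 180), chol = c(3, 8))

#' Ten-year SCORE cardiovascular risk (low-risk region, total cholesterol)
#'
#' Evaluates the SCORE Weibull survival equations for coronary and
#' non-coronary cardiovascular mortality and returns their summed 10-year
#' risk, in percent. The baseline survival for each cause is
#' `S0(a) = exp(-exp(alpha) * (a - 20)^p)`; risk factors act proportionally
#' through `w = b_chol (chol - 6) + b_sbp (SBP - 120) + b_smoker smoker`, and
#' the 10-year risk is `1 - S(age + 10)/S(age)` with `S = S0^exp(w)`.
#' Inputs outside the model's validity window (age 20-65, SBP 100-180 mmHg,
#' total cholesterol 3-8 mmol/l) are clipped with a warning. Missing inputs
#' yield `NA` (the assessment is reported as "not reported" downstream rather
#' than failing).
#'
#' This is the mortality-based SCORE output; the program used it as the
#' common yardstick for 10-year cardiovascular risk.
#'
#' @param age Age in years (typically the [adjusted_age()]).
#' @param sex `"male"` or `"female"`.
#' @param sbp Systolic blood pressure, mmHg.
#' @param total_chol Total cholesterol, mmol/l.
#' @param smoker Logical: current smoker.
#' @return Numeric vector of 10-year risks in percent.
#' @examples
#' score_risk(53.2, "male", 125, 5.0, FALSE)
#' @export
score_risk <- function(age, sex, sbp, total_chol, smoker) {
  n <- max(length(age), length(sex), length(sbp), length(total_chol),
           length(smoker))
  age <- rep_len(age, n); sex <- rep_len(sex, n); sbp <- rep_len(sbp, n)
  total_chol <- rep_len(total_chol, n); smoker <- rep_len(smoker, n)
  if (!all(sex %in% c("male", "female") | is.na(sex))) {
    abort_sc("sex must be \"male\" or \"female\".", "invalid_measurement")
  }
  clip <- function(x, lim, what) {
    out_of_range <- is.finite(x) & (x < lim[1] | x > lim[2])
    if (any(out_of_range)) {
      rlang::warn(sprintf(
        "%d %s value(s) outside the SCORE validity range [%g, %g] were clipped.",
        sum(out_of_range), what, lim[1], lim[2]))
    }
    pmin(pmax(x, lim[1]), lim[2])
  }
  age <- clip(age, score_limits$age, "age")
  sbp <- clip(sbp, score_limits$sbp, "SBP")
  total_chol <- clip(total_chol, score_limits$chol, "cholesterol")
  risk_cause <- function(cause) {
    co <- vapply(sex, function(s) {
      if (is.na(s)) c(NA_real_, NA_real_) else score_coefs[[s]][[cause]]
    }, numeric(2))
    alpha <- co[1, ]; p <- co[2, ]
    b <- score_coefs$beta[[cause]]
    w <- b["chol"] * (total_chol - 6) + b["sbp"] * (sbp - 120) +
      b["smoker"] * as.numeric(smoker)
    s_now <- exp(-exp(alpha) * (age - 20)^p)^exp(w)
    s_10 <- exp(-exp(alpha) * (age - 10)^p)^exp(w)
    unname(1 - s_10 / s_now)
  }
  100 * (risk_cause("chd") + risk_cause("nonchd"))
}

#' Categorize a 10-year cardiovascular risk
#'
#' Left-closed bands matching the program's reporting: `[0, 10)` percent is
#' low, `[10, 20)` mid, `>= 20` high. Missing risks map to `"not_reported"`.
#'
#' @param risk_pct Numeric vector of risks in percent (non-negative).
#' @return Character vector with levels `"low_0_10"`, `"mid_10_20"`,
#'   `"high_ge_20"`, `"not_reported"`.
#' @examples
#' risk_category(c(5, 10, 20, NA))
#' @export
risk_category <- function(risk_pct) {
  if (any(risk_pct < 0, na.rm = TRUE)) {
    abort_sc("risk percentages must be non-negative.", "invalid_measurement")
  }
  dplyr::case_when(
    is.na(risk_pct) ~ "not_reported",
    risk_pct < 10 ~ "low_0_10",
    risk_pct < 20 ~ "mid_10_20",
    TRUE ~ "high_ge_20"
  )
}

#' Metabolic-syndrome classification (male NCEP-ATP III)
#'
#' A patient is classified as having the metabolic syndrome when at least
#' three of five criteria are met: waist circumference > 102 cm;
#' triglycerides >= 1.7 mmol/l; HDL cholesterol < 1.03 mmol/l; blood pressure
#' >= 130/85 mmHg or antihypertensive medication; fasting glucose
#' >= 5.6 mmol/l or antidiabetic medication. The male thresholds are used
#' throughout (the program population is male). When any criterion input is
#' missing the classification is indeterminate (`NA`) and the patient is
#' excluded from prevalence denominators.
#'
#' @param measurements Data frame with columns `waist_cm`,
#'   `triglycerides_mmol_l`, `hdl_mmol_l`, `sbp_mmHg`, `dbp_mmHg`,
#'   `glucose_mmol_l`, `on_antihypertensive`, `on_antidiabetic`.
#' @return Logical vector (`NA` = indeterminate).
#' @examples
#' metabolic_syndrome(data.frame(
#'   waist_cm = 92, triglycerides_mmol_l = 1.3, hdl_mmol_l = 1.3,
#'   sbp_mmHg = 125, dbp_mmHg = 78, glucose_mmol_l = 5.3,
#'   on_antihypertensive = FALSE, on_antidiabetic = FALSE))
#' @export
metabolic_syndrome <- function(measurements) {
  m <- measurements
  crit <- cbind(
    m$waist_cm > 102,
    m$triglycerides_mmol_l >= 1.7,
    m$hdl_mmol_l < 1.03,
    m$sbp_mmHg >= 130 | m$dbp_mmHg >= 85 | m$on_antihypertensive,
    m$glucose_mmol_l >= 5.6 | m$on_antidiabetic
  )
  n_met <- rowSums(crit)
  ifelse(is.na(n_met), NA, n_met >= 3)
}

#' Guideline-style lifestyle and medication advice
#'
#' Minimal, explicitly configurable advice rules consistent with the
#' program's reporting: stop smoking for smokers; lose weight when BMI >= 25
#' or waist > 102 cm; more exercise when any metabolic-syndrome criterion is
#' met or the risk category is not low; new medication when the risk category
#' is high and the patient is not already on antihypertensive or statin
#' therapy. These are reporting heuristics, not a reproduction of guideline
#' text.
#'
#' @param assessment A data frame as returned by [assess_cvrm()].
#' @param bmi_cut,waist_cut Thresholds for the weight advice.
#' @return A list column-compatible list of character vectors, one per row.
#' @export
advise <- function(assessment, bmi_cut = 25, waist_cut = 102) {
  m <- assessment
  any_mets_crit <-
    (m$waist_cm > 102) | (m$triglycerides_mmol_l >= 1.7) |
    (m$hdl_mmol_l < 1.03) |
    (m$sbp_mmHg >= 130 | m$dbp_mmHg >= 85 | m$on_antihypertensive) |
    (m$glucose_mmol_l >= 5.6 | m$on_antidiabetic)
  purrr::map(seq_len(nrow(m)), function(i) {
    adv <- character()
    if (isTRUE(m$smoker[i])) adv <- c(adv, "stop_smoking")
    if (isTRUE(m$bmi[i] >= bmi_cut) || isTRUE(m$waist_cm[i] > waist_cut)) {
      adv <- c(adv, "lose_weight")
    }
    if (isTRUE(any_mets_crit[i]) ||
        (!is.na(m$risk_category[i]) &&
         m$risk_category[i] %in% c("mid_10_20", "high_ge_20"))) {
      adv <- c(adv, "more_exercise")
    }
    if (identical(m$risk_category[i], "high_ge_20") &&
        !isTRUE(m$on_antihypertensive[i]) && !isTRUE(m$on_statin[i])) {
      adv <- c(adv, "new_medication")
    }
    adv
  })
}

#' One-stop cardiovascular risk work-up
#'
#' Takes a measurements table (one row per assessment), applies the survivor
#' age adjustment, evaluates the SCORE risk, categorizes it, classifies the
#' metabolic syndrome and attaches advice. Rows with missing SCORE inputs get
#' `risk_category = "not_reported"` instead of failing.
#'
#' @param measurements Data frame with at least `age_years`, `sex`,
#'   `sbp_mmHg`, `total_chol_mmol_l`, `smoker` plus the metabolic-syndrome
#'   inputs.
#' @return The input tibble with `adjusted_age_years`, `score_risk_pct`,
#'   `risk_category`, `metabolic_syndrome` and `advice` (list column)
#'   appended.
#' @examples
#' m <- generate_measurements(cohort_config(seed = 1), n = 5)
#' assess_cvrm(m)
#' @export
assess_cvrm <- function(measurements) {
  m <- tibble::as_tibble(measurements)
  m$adjusted_age_years <- adjusted_age(m$age_years)
  complete <- !(is.na(m$adjusted_age_years) | is.na(m$sex) | is.na(m$sbp_mmHg) |
                is.na(m$total_chol_mmol_l) | is.na(m$smoker))
  m$score_risk_pct <- NA_real_
  if (any(complete)) {
    m$score_risk_pct[complete] <- score_risk(
      m$adjusted_age_years[complete], m$sex[complete], m$sbp_mmHg[complete],
      m$total_chol_mmol_l[complete], m$smoker[complete])
  }
  m$risk_category <- risk_category(m$score_risk_pct)
  m$metabolic_syndrome <- metabolic_syndrome(m)
  m$advice <- advise(m)
  m
}
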