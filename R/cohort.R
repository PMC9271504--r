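#' Configuration of the synthetic shared-care cohort generator
#'
#' All generator targets live here; nothing is hard-coded downstream. The
#' defaults encode the shared-care program's study conditions: 162 patients
#' accrued between October 2012 and January 2017, a 2-year per-patient
#' follow-up horizon with primary-care visits at months 3, 9, 15 and 21 and
#' oncology visits (CT at 6, 12 and 24 months) in between, dropout 30/162,
#' relapse 6/162, per-visit incident rates 26/364 (hemolysis LDH re-tests),
#' 81/364 (reports later than 21 days), 73/364 (reports within a day), a
#' program-observed per-evaluable-patient failure probability of 4/113 with
#' failure kinds mixed 3:1 between uncontactable missed appointments and
#' undetected wrong-marker panels, measurement distributions keyed to the
#' program's reported medians and ranges, and HADS-A responses calibrated to
#' mean 3.2 with 6.4% of patients at or above the anxiety cutoff.
#'
#' Continuous measurement distributions are parameterized from a (median,
#' range) pair by a range-matching recipe: with `z = qnorm(1 - 1/(2 n_ref))`
#' the expected extremes of `n_ref` draws sit near median +/- z standard
#' deviations, so `sd = (hi - lo) / (2 z)` for (truncated) normal variables
#' and `sdlog = log(hi/lo) / (2 z)` for log-normal ones, with `n_ref = 140`
#' assessments.
#'
#' @param n_patients Number of patients to enroll.
#' @param accrual_start,accrual_end Accrual window (coerced to `Date`).
#' @param followup_horizon_years Per-patient follow-up horizon.
#' @param p_failure Per-evaluable-patient probability of a detection failure.
#' @param p_dropout Probability a patient stops shared care early (censored).
#' @param relapse_rate Probability of a (timely detected) relapse.
#' @param rate_hemolysis Per-primary-care-visit probability of a
#'   hemolysis-suspect LDH elevation (re-tested).
#' @param rate_late_report Per-visit probability the report returns after
#'   more than 21 days.
#' @param rate_same_day_report Per-visit probability the report returns
#'   within 1 day.
#' @param rate_wrong_marker,rate_missed_uncontactable Observed per-visit
#'   rates of the two organizational failure mechanisms; their ratio sets the
#'   failure-kind mix.
#' @param p_wrong_marker_undetected Probability a generated wrong-marker
#'   panel goes unnoticed by the case manager (an undetected one is a
#'   failure).
#' @param p_hemolysis_retest_late Probability a hemolysis re-test takes more
#'   than 14 days.
#' @param p_referral Per-visit probability of a benign abnormal finding with
#'   timely referral.
#' @param cvrm_coverage Probability a patient's primary-care visits include
#'   cardiovascular risk management.
#' @param visit_schedule List with `primary_care`, `oncology` and `ct` month
#'   vectors.
#' @param measurement_params Data frame of distribution targets (variable,
#'   family, median, lo, hi); see Details.
#' @param n_ref Reference sample size for the range-matching recipe.
#' @param p_smoker,p_antihypertensive,p_statin,p_antidiabetic Categorical
#'   measurement rates.
#' @param hads_mean Target mean HADS-A score.
#' @param hads_flag Target fraction of patients at or above the anxiety
#'   cutoff.
#' @param hads_shift Expected follow-up shift of the HADS-A score (score
#'   points; 0 = stable anxiety).
#' @param rand36_shift Expected follow-up shift of the RAND-36 latent health
#'   (0-100 scale).
#' @param seed Integer seed; the generator is fully reproducible.
#' @return An object of class `sc_cohort_config` (a list).
#' @export
cohort_config <- function(n_patients = 162,
                          accrual_start = "2012-10-01",
                          accrual_end = "2017-01-31",
                          followup_horizon_years = 2,
                          p_failure = 4 / 113,
                          p_dropout = 30 / 162,
                          relapse_rate = 6 / 162,
                          rate_hemolysis = 26 / 364,
                          rate_late_report = 81 / 364,
                          rate_same_day_report = 73 / 364,
                          rate_wrong_marker = 1 / 364,
                          rate_missed_uncontactable = 3 / 364,
                          p_wrong_marker_undetected = 1,
                          p_hemolysis_retest_late = 0,
                          p_referral = 1 / 364,
                          cvrm_coverage = 140 / 162,
                          visit_schedule = list(primary_care = c(3, 9, 15, 21),
                                                oncology = c(6, 12, 18, 24),
                                                ct = c(6, 12, 24)),
                          measurement_params = default_measurement_params(),
                          n_ref = 140,
                          p_smoker = 0.22,
                          p_antihypertensive = 10 / 140,
                          p_statin = 2 / 140,
                          p_antidiabetic = 2 / 140,
                          hads_mean = 3.2,
                          hads_flag = 0.064,
                          hads_shift = 0,
                          rand36_shift = 0,
                          seed = 20121001) {
  probs <- c(p_failure = p_failure, p_dropout = p_dropout,
             relapse_rate = relapse_rate, rate_hemolysis = rate_hemolysis,
             rate_late_report = rate_late_report,
             rate_same_day_report = rate_same_day_report,
             rate_wrong_marker = rate_wrong_marker,
             rate_missed_uncontactable = rate_missed_uncontactable,
             p_wrong_marker_undetected = p_wrong_marker_undetected,
             p_hemolysis_retest_late = p_hemolysis_retest_late,
             p_referral = p_referral, cvrm_coverage = cvrm_coverage,
             p_smoker = p_smoker, hads_flag = hads_flag)
  for (nm in names(probs)) check_prob(probs[[nm]], nm, open = FALSE)
  if (p_dropout + relapse_rate >= 1) {
    abort_sc("p_dropout + relapse_rate must be below 1.", "invalid_config")
  }
  horizon_months <- 12 * followup_horizon_years
  if (sum(visit_schedule$primary_care <= horizon_months) < 2) {
    abort_sc(paste0("infeasible schedule: the follow-up horizon must cover ",
                    "at least two primary-care visits."), "invalid_config")
  }
  structure(
    c(list(n_patients = as.integer(n_patients),
           accrual_start = as.Date(accrual_start),
           accrual_end = as.Date(accrual_end),
           followup_horizon_years = followup_horizon_years,
           visit_schedule = visit_schedule,
           measurement_params = measurement_params,
           n_ref = n_ref,
           p_antihypertensive = p_antihypertensive,
           p_statin = p_statin, p_antidiabetic = p_antidiabetic,
           hads_mean = hads_mean, hads_shift = hads_shift,
           rand36_shift = rand36_shift, seed = seed),
      as.list(probs)),
    class = "sc_cohort_config"
  )
}

#' Default measurement distribution targets
#'
#' One row per continuous measurement: distribution family and the reported
#' median and range it is keyed to. Total cholesterol is not tabulated by the
#' program reports, so a log-normal with median 5.0 mmol/l and a typical
#' spread is synthesized; BMI and HbA1c likewise use conventional values.
#'
#' @return A tibble with columns `variable`, `family`, `median`, `lo`, `hi`.
#' @export
default_measurement_params <- function() {
  tibble::tribble(
    ~variable,              ~family,     ~median, ~lo,   ~hi,
    "age_years",            "lognormal", 38.2,    20.5,  75.7,
    "sbp_mmHg",             "normal",    125,     95,    166,
    "dbp_mmHg",             "normal",    78,      50,    109,
    "waist_cm",             "normal",    92,      67,    128,
    "hdl_mmol_l",           "lognormal", 1.30,    0.7,   9.0,
    "triglycerides_mmol_l", "lognormal", 1.30,    0.48,  6.0,
    "glucose_mmol_l",       "lognormal", 5.3,     3.3,   8.1,
    "total_chol_mmol_l",    "lognormal", 5.0,     3.2,   7.8,
    "bmi",                  "lognormal", 25.5,    18.5,  36,
    "hba1c",                "normal",    5.4,     4.4,   6.6
  )
}

# one draw vector per configured variable, medians pinned by construction
draw_measurement <- function(params, n, n_ref) {
  z <- stats::qnorm(1 - 1 / (2 * n_ref))
  out <- lapply(seq_len(nrow(params)), function(i) {
    p <- params[i, ]
    if (p$family == "lognormal") {
      sdlog <- log(p$hi / p$lo) / (2 * z)
      stats::rlnorm(n, meanlog = log(p$median), sdlog = sdlog)
    } else {
      sd <- (p$hi - p$lo) / (2 * z)
      x <- stats::rnorm(n, mean = p$median, sd = sd)
      # resample the rare draws outside the plausible span
      bad <- x < p$lo - 2 * sd | x > p$hi + 2 * sd
      while (any(bad)) {
        x[bad] <- stats::rnorm(sum(bad), mean = p$median, sd = sd)
        bad <- x < p$lo - 2 * sd | x > p$hi + 2 * sd
      }
      x
    }
  })
  names(out) <- params$variable
  tibble::as_tibble(out)
}

#' Generate a synthetic cardiovascular measurements table
#'
#' Draws `n` assessment rows from the configured distribution targets:
#' log-normal for skewed positive variables (lipids, glucose, age, BMI) and
#' truncated normal for pressures and waist circumference, each pinned to its
#' reported median; categorical rates (smoking, medication) as configured.
#' Weight is derived from BMI and a synthesized height so the two stay
#' consistent.
#'
#' @param config An [cohort_config()].
#' @param n Number of rows.
#' @param seed Optional seed override (defaults to `config$seed + 1`).
#' @return A tibble of `CvrmMeasurements` rows.
#' @examples
#' generate_measurements(cohort_config(seed = 1), n = 3)
#' @export
generate_measurements <- function(config, n, seed = NULL) {
  stopifnot(inherits(config, "sc_cohort_config"), n >= 1)
  set.seed(as.integer((if (is.null(seed)) config$seed + 1 else seed) %% 2147483647))
  m <- draw_measurement(config$measurement_params, n, config$n_ref)
  m$age_years <- pmax(m$age_years, 18.1)
  height_m <- stats::rnorm(n, 1.82, 0.07)
  m$weight_kg <- m$bmi * height_m^2
  m$sex <- rep("male", n)
  m$smoker <- stats::runif(n) < config$p_smoker
  m$on_antihypertensive <- stats::runif(n) < config$p_antihypertensive
  m$on_statin <- stats::runif(n) < config$p_statin
  m$on_antidiabetic <- stats::runif(n) < config$p_antidiabetic
  dplyr::select(m, "age_years", "sex", "sbp_mmHg", "dbp_mmHg", "waist_cm",
                "weight_kg", "bmi", "hdl_mmol_l", "total_chol_mmol_l",
                "triglycerides_mmol_l", "glucose_mmol_l", "hba1c", "smoker",
                "on_antihypertensive", "on_statin", "on_antidiabetic")
}

#' Generate a synthetic follow-up ledger
#'
#' Simulates the shared-care program: enrollment over the accrual window,
#' alternating primary-care and oncology visits on the configured schedule,
#' early dropout (censoring), timely detected relapses, per-visit logistics
#' incidents (hemolysis LDH re-tests, late and same-day report returns,
#' benign referrals), and per-evaluable-patient detection failures realized
#' either as an uncontactable missed appointment or as an undetected
#' wrong-marker panel at a randomly chosen primary-care visit. Failures are
#' assigned among patients who neither drop out nor relapse, so the evaluable
#' failure fraction recovers `p_failure` by construction.
#'
#' @param config An [cohort_config()].
#' @return An `sc_ledger`: list with `patients`, `visits`, `incidents`
#'   tibbles and the generating `config`.
#' @examples
#' led <- generate_cohort(cohort_config(n_patients = 20, seed = 1))
#' dplyr::count(led$visits, setting)
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "sc_cohort_config"))
  set.seed(as.integer(config$seed %% 2147483647))
  n <- config$n_patients
  horizon_m <- 12 * config$followup_horizon_years
  ids <- sprintf("P%04d", seq_len(n))
  span <- as.numeric(config$accrual_end - config$accrual_start)
  enroll <- config$accrual_start + sort(sample.int(span + 1, n, replace = TRUE) - 1)

  u <- stats::runif(n)
  status <- ifelse(u < config$p_dropout, "censored",
                   ifelse(u < config$p_dropout + config$relapse_rate,
                          "relapsed", "completed_2y"))
  exit_month <- dplyr::case_when(
    status == "censored" ~ stats::runif(n, 1, horizon_m),
    status == "relapsed" ~ stats::runif(n, min(config$visit_schedule$oncology),
                                        horizon_m),
    TRUE ~ as.numeric(horizon_m)
  )
  fails <- status == "completed_2y" & stats::runif(n) < config$p_failure
  kind_w <- c(missed_uncontactable = config$rate_missed_uncontactable,
              wrong_marker = config$rate_wrong_marker)
  fail_kind <- ifelse(fails,
                      sample(names(kind_w), n, replace = TRUE,
                             prob = kind_w / sum(kind_w)),
                      NA_character_)

  prior_fu <- stats::rlnorm(n, log(3.3),
                            log(11.5 / 0.6) / (2 * stats::qnorm(1 - 1 / (2 * config$n_ref))))
  cvrm_covered <- stats::runif(n) < config$cvrm_coverage

  one_patient <- function(i) {
    sched <- dplyr::bind_rows(
      tibble::tibble(month = config$visit_schedule$primary_care,
                     setting = "primary_care"),
      tibble::tibble(month = config$visit_schedule$oncology,
                     setting = "oncology")
    ) |>
      dplyr::filter(.data$month <= exit_month[i] | (.data$month <= horizon_m &
                                                    status[i] == "completed_2y")) |>
      dplyr::arrange(.data$month)
    if (nrow(sched) == 0) return(list(visits = NULL, incidents = NULL))
    nv <- nrow(sched)
    visit_date <- enroll[i] + round(sched$month * 30.44)
    is_pc <- sched$setting == "primary_care"

    markers <- rep("AFP;bHCG;LDH", nv)
    panel_ok <- rep(TRUE, nv)
    detected <- rep(NA, nv)
    abnormal <- rep(FALSE, nv)
    action_lag <- rep(NA_real_, nv)
    hemolysis <- is_pc & stats::runif(nv) < config$rate_hemolysis
    retest_lag <- ifelse(hemolysis,
                         ifelse(stats::runif(nv) < config$p_hemolysis_retest_late,
                                sample(15:28, nv, replace = TRUE),
                                sample(2:14, nv, replace = TRUE)),
                         NA_real_)
    rr <- stats::runif(nv)
    report_lag <- ifelse(is_pc,
                         ifelse(rr < config$rate_same_day_report,
                                sample(0:1, nv, replace = TRUE),
                                ifelse(rr < config$rate_same_day_report +
                                         config$rate_late_report,
                                       sample(22:60, nv, replace = TRUE),
                                       sample(2:21, nv, replace = TRUE))),
                         NA_real_)
    incidents <- tibble::tibble(patient_id = character(),
                                incident_date = as.Date(character()),
                                kind = character(),
                                contact_lag_days = double())

    # benign referral with timely action
    ref <- is_pc & stats::runif(nv) < config$p_referral
    abnormal[ref] <- TRUE
    action_lag[ref] <- sample(1:14, sum(ref), replace = TRUE)
    if (any(ref)) {
      incidents <- dplyr::bind_rows(incidents, tibble::tibble(
        patient_id = ids[i], incident_date = visit_date[ref],
        kind = "referral", contact_lag_days = NA_real_))
    }

    # relapse detected (timely) at the last oncology visit before exit
    if (status[i] == "relapsed" && any(!is_pc)) {
      j <- max(which(!is_pc))
      abnormal[j] <- TRUE
      action_lag[j] <- sample(1:14, 1)
      incidents <- dplyr::bind_rows(incidents, tibble::tibble(
        patient_id = ids[i], incident_date = visit_date[j],
        kind = "relapse_detected", contact_lag_days = NA_real_))
    }

    # the patient's failure mechanism, at a random primary-care visit
    if (fails[i]) {
      j <- sample(which(is_pc), 1)
      if (fail_kind[i] == "wrong_marker") {
        undet <- stats::runif(1) < config$p_wrong_marker_undetected
        markers[j] <- "AFP;LDH"
        panel_ok[j] <- FALSE
        detected[j] <- !undet
        if (undet) {
          incidents <- dplyr::bind_rows(incidents, tibble::tibble(
            patient_id = ids[i], incident_date = visit_date[j],
            kind = "wrong_marker_unnoticed", contact_lag_days = NA_real_))
        }
      } else {
        incidents <- dplyr::bind_rows(incidents, tibble::tibble(
          patient_id = ids[i], incident_date = visit_date[j],
          kind = "missed_appointment_uncontactable",
          contact_lag_days = sample(15:28, 1)))
      }
    }

    # late-report incidents mirror the report lags (logistics, not failures)
    late <- is_pc & !is.na(report_lag) & report_lag > 21
    if (any(late)) {
      incidents <- dplyr::bind_rows(incidents, tibble::tibble(
        patient_id = ids[i], incident_date = visit_date[late],
        kind = "late_report", contact_lag_days = NA_real_))
    }

    visits <- tibble::tibble(
      patient_id = ids[i],
      visit_date = visit_date,
      setting = sched$setting,
      markers_ordered = markers,
      marker_panel_correct = panel_ok,
      marker_error_detected_by_case_manager = ifelse(panel_ok, NA, detected),
      abnormal_finding = abnormal,
      action_lag_days = action_lag,
      ldh_elevated_hemolysis_suspected = hemolysis,
      retest_lag_days = retest_lag,
      report_return_lag_days = report_lag,
      cvrm_performed = is_pc & cvrm_covered[i],
      duration_min = pmin(pmax(round(stats::rlnorm(nv, log(20), 0.25)), 10), 60)
    )
    list(visits = visits, incidents = incidents)
  }

  parts <- lapply(seq_len(n), one_patient)
  visits <- dplyr::bind_rows(lapply(parts, `[[`, "visits"))
  incidents <- dplyr::bind_rows(lapply(parts, `[[`, "incidents"))
  patients <- tibble::tibble(
    patient_id = ids,
    enrollment_date = enroll,
    prior_followup_years = round(prior_fu, 1),
    status = status,
    censor_date = dplyr::if_else(status == "censored",
                                 enroll + round(exit_month * 30.44),
                                 as.Date(NA))
  )
  structure(list(patients = patients, visits = visits, incidents = incidents,
                 config = config),
            class = c("sc_ledger", "list"))
}

#' @export
print.sc_ledger <- function(x, ...) {
  cat("<sc_ledger>\n")
  cat(sprintf("  %d patients, %d visits, %d incidents\n",
              nrow(x$patients), nrow(x$visits), nrow(x$incidents)))
  invisible(x)
}

# beta-binomial parameters for the HADS-A generator: items ~ Binomial(3, p)
# with p ~ Beta(a, b); the 7-item sum is then beta-binomial(21, a, b).
# `a` is solved so that P(sum >= cutoff) hits the flag target while
# 21 a / (a + b) equals the target mean.
hads_betabin_params <- function(mean, flag, cutoff = 8) {
  stopifnot(mean > 0, mean < 21)
  b_of <- function(a) a * (21 - mean) / mean
  dbb <- function(k, a, b) {
    exp(lchoose(21, k) + lbeta(k + a, 21 - k + b) - lbeta(a, b))
  }
  tail <- function(a) sum(dbb(cutoff:21, a, b_of(a)))
  root <- tryCatch(
    stats::uniroot(function(a) tail(a) - flag, c(0.05, 500))$root,
    error = function(e) {
      abort_sc(sprintf(
        "no beta-binomial with mean %.3g reaches a flag fraction of %.3g.",
        mean, flag), "hads_calibration")
    }
  )
  c(a = root, b = b_of(root))
}

#' Generate synthetic HADS-A and RAND-36 responses
#'
#' HADS-A items are drawn from a patient-level beta-binomial model: each
#' patient gets a latent item propensity `p ~ Beta(a, b)` with `(a, b)`
#' solved so that the scored 7-item sum has the configured mean and flag
#' fraction; the seven items are then Binomial(3, p). The follow-up
#' administration reuses the patient's latent propensity (pairing) shifted by
#' `hads_shift / 21`, so a zero shift reproduces the baseline distribution.
#' RAND-36 items are generated from a latent health score per patient
#' (Beta-distributed on 0-100, follow-up shifted by `rand36_shift`), each raw
#' item category chosen nearest to a noisy copy of the latent score.
#'
#' @param config An [cohort_config()].
#' @param patients Patients table (only `patient_id` is used).
#' @param seed Optional seed override (defaults to `config$seed + 2`).
#' @return A list with `hads` and `rand36` item-level tibbles, each holding a
#'   `baseline` and a `followup` administration per patient.
#' @examples
#' led <- generate_cohort(cohort_config(n_patients = 5, seed = 1))
#' q <- generate_questionnaires(cohort_config(n_patients = 5, seed = 1),
#'                              led$patients)
#' hads_a_score(q$hads)
#' @export
generate_questionnaires <- function(config, patients, seed = NULL) {
  stopifnot(inherits(config, "sc_cohort_config"))
  if (nrow(patients) == 0) abort_sc("patients table is empty.", "schema")
  set.seed(as.integer((if (is.null(seed)) config$seed + 2 else seed) %% 2147483647))
  n <- nrow(patients)
  ab <- hads_betabin_params(config$hads_mean, config$hads_flag)
  p_base <- stats::rbeta(n, ab["a"], ab["b"])
  p_fu <- pmin(pmax(p_base + config$hads_shift / 21, 0), 1)
  draw_items <- function(p) {
    m <- matrix(stats::rbinom(n * 7, size = 3, prob = rep(p, each = 7)),
                nrow = n, byrow = TRUE)
    colnames(m) <- paste0("item_a", 1:7)
    tibble::as_tibble(m)
  }
  hads <- dplyr::bind_rows(
    dplyr::bind_cols(tibble::tibble(patient_id = patients$patient_id,
                                    administration_label = "baseline"),
                     draw_items(p_base)),
    dplyr::bind_cols(tibble::tibble(patient_id = patients$patient_id,
                                    administration_label = "followup"),
                     draw_items(p_fu))
  )

  health <- 100 * stats::rbeta(n, 5, 1.6)
  draw_rand <- function(h) {
    cols <- lapply(1:36, function(j) {
      k <- rand36_recode_key[[j]]
      target <- pmin(pmax(h + stats::rnorm(n, 0, 15), 0), 100)
      vapply(target, function(t) which.min(abs(k - t)), integer(1))
    })
    names(cols) <- sprintf("item_%02d", 1:36)
    tibble::as_tibble(cols)
  }
  rand36 <- dplyr::bind_rows(
    dplyr::bind_cols(tibble::tibble(patient_id = patients$patient_id,
                                    administration_label = "baseline"),
                     draw_rand(health)),
    dplyr::bind_cols(tibble::tibble(patient_id = patients$patient_id,
                                    administration_label = "followup"),
                     draw_rand(pmin(pmax(health + config$rand36_shift, 0), 100)))
  )
  list(hads = hads, rand36 = rand36)
}
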