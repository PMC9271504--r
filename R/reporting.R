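#' Plot-ready trajectory of a monitoring run
#'
#' One row per evaluable outcome with the cumulative log-likelihood-ratio
#' statistic, both boundary thresholds (also expressed as failure counts as a
#' function of evaluable patients, the scale on which the monitoring chart is
#' drawn), and a flag marking the crossing row.
#'
#' @param result An `sc_monitoring` (or `sc_state`) object.
#' @param boundary An `sc_boundary`; defaults to the one stored in `result`.
#' @return A tibble with columns `n_evaluable`, `n_failures`, `cum_llr`,
#'   `log_lower`, `log_upper`, `fail_bound_safe`, `fail_bound_unsafe`,
#'   `crossed`.
#' @export
trajectory_series <- function(result, boundary = NULL) {
  state <- if (inherits(result, "sc_monitoring")) result$final_state else result
  if (is.null(boundary)) {
    if (!inherits(result, "sc_monitoring")) {
      abort_sc("supply a boundary when `result` is a bare state.", "schema")
    }
    boundary <- result$boundary
  }
  tr <- state$trajectory
  if (nrow(tr) == 0) {
    return(tibble::tibble(n_evaluable = integer(), n_failures = integer(),
                          cum_llr = double(), log_lower = double(),
                          log_upper = double(), fail_bound_safe = double(),
                          fail_bound_unsafe = double(), crossed = logical()))
  }
  a <- boundary$llr_failure
  b <- boundary$llr_success
  tr |>
    dplyr::mutate(
      log_lower = boundary$log_lower,
      log_upper = boundary$log_upper,
      # cum_llr = f*a + (n-f)*b, so the boundary in failure-count space is
      # f(n) = (threshold - n*b) / (a - b)
      fail_bound_safe = (boundary$log_lower - .data$n_evaluable * b) / (a - b),
      fail_bound_unsafe = (boundary$log_upper - .data$n_evaluable * b) / (a - b),
      crossed = .data$cum_llr >= boundary$log_upper |
        .data$cum_llr <= boundary$log_lower
    )
}

#' Logistics metrics of the primary-care visits
#'
#' Report-return delays and re-test burden are tracked separately from the
#' safety failures: a late report is a logistics matter, never a failure.
#' Percentages are reported raw, rounded half-up to integer (as printed) and
#' at one decimal.
#'
#' @param visits Visits table.
#' @return A tibble with one row per metric: `metric`, `n`, `denominator`,
#'   `value` (raw percent, or minutes for the duration row), `display`
#'   (integer half-up percent) and `one_decimal`.
#' @examples
#' led <- example_cohort_ledger()
#' logistics_metrics(led$visits)
#' @export
logistics_metrics <- function(visits) {
  pc <- dplyr::filter(visits, .data$setting == "primary_care")
  denom <- nrow(pc)
  if (denom == 0) {
    return(tibble::tibble(metric = c("pct_reports_late_21d",
                                     "pct_reports_within_1d",
                                     "pct_ldh_retests", "median_visit_min"),
                          n = NA_integer_, denominator = 0L,
                          value = NA_real_, display = NA_real_,
                          one_decimal = NA_real_))
  }
  counts <- c(
    pct_reports_late_21d = sum(pc$report_return_lag_days > 21, na.rm = TRUE),
    pct_reports_within_1d = sum(pc$report_return_lag_days <= 1, na.rm = TRUE),
    pct_ldh_retests = sum(pc$ldh_elevated_hemolysis_suspected, na.rm = TRUE)
  )
  pct <- unname(100 * counts / denom)
  dplyr::bind_rows(
    tibble::tibble(metric = names(counts), n = as.integer(counts),
                   denominator = as.integer(denom), value = pct,
                   display = round_half_up(pct),
                   one_decimal = round_half_up(pct, 1)),
    tibble::tibble(metric = "median_visit_min", n = NA_integer_,
                   denominator = as.integer(denom),
                   value = stats::median(pc$duration_min),
                   display = stats::median(pc$duration_min),
                   one_decimal = stats::median(pc$duration_min))
  )
}

#' Cohort flow counts
#'
#' Partition of the enrolled patients by final program status.
#'
#' @param patients Patients table.
#' @return A one-row tibble: `enrolled`, `completed_2y`, `stopped`,
#'   `relapsed`, `active`. The four status counts sum to `enrolled`.
#' @export
cohort_flow <- function(patients) {
  if (nrow(patients) && !all(patients$status %in% patient_statuses)) {
    abort_sc("patients$status contains unknown levels.", "schema")
  }
  tibble::tibble(
    enrolled = nrow(patients),
    completed_2y = sum(patients$status == "completed_2y"),
    stopped = sum(patients$status == "censored"),
    relapsed = sum(patients$status == "relapsed"),
    active = sum(patients$status == "active")
  )
}

#' Program-style summary table of CVRM assessments
#'
#' Builds the reporting table for a set of assessed measurements: continuous
#' rows as median and range, categorical rows as n / denominator with the
#' percent under the half-up display rule (integer and one decimal).
#' Indeterminate metabolic-syndrome classifications are excluded from that
#' row's denominator; assessments without a computed risk are the
#' `not_reported` category.
#'
#' @param assessments A tibble from [assess_cvrm()].
#' @return A tibble of rows `(label, n, denominator, percent, percent_1dp,
#'   median, range_lo, range_hi)` with `NA` where a field does not apply.
#' @export
summarize_cvrm <- function(assessments) {
  a <- assessments
  cont_row <- function(label, x) {
    tibble::tibble(label = label, n = NA_integer_, denominator = NA_integer_,
                   percent = NA_real_, percent_1dp = NA_real_,
                   median = stats::median(x, na.rm = TRUE),
                   range_lo = suppressWarnings(min(x, na.rm = TRUE)),
                   range_hi = suppressWarnings(max(x, na.rm = TRUE)))
  }
  cat_row <- function(label, n, denom) {
    pct <- if (denom > 0) 100 * n / denom else NA_real_
    tibble::tibble(label = label, n = as.integer(n),
                   denominator = as.integer(denom),
                   percent = round_half_up(pct),
                   percent_1dp = round_half_up(pct, 1),
                   median = NA_real_, range_lo = NA_real_, range_hi = NA_real_)
  }
  n_all <- nrow(a)
  mets_known <- sum(!is.na(a$metabolic_syndrome))
  adv <- table(factor(unlist(a$advice),
                      levels = c("stop_smoking", "lose_weight",
                                 "more_exercise", "new_medication")))
  dplyr::bind_rows(
    cont_row("age_years", a$age_years),
    cont_row("sbp_mmHg", a$sbp_mmHg),
    cont_row("dbp_mmHg", a$dbp_mmHg),
    cont_row("waist_cm", a$waist_cm),
    cont_row("hdl_mmol_l", a$hdl_mmol_l),
    cont_row("triglycerides_mmol_l", a$triglycerides_mmol_l),
    cont_row("glucose_mmol_l", a$glucose_mmol_l),
    cat_row("current_smoker", sum(a$smoker, na.rm = TRUE), n_all),
    cat_row("metabolic_syndrome",
            sum(a$metabolic_syndrome, na.rm = TRUE), mets_known),
    cat_row("risk_low_0_10", sum(a$risk_category == "low_0_10"), n_all),
    cat_row("risk_mid_10_20", sum(a$risk_category == "mid_10_20"), n_all),
    cat_row("risk_high_ge_20", sum(a$risk_category == "high_ge_20"), n_all),
    cat_row("risk_not_reported", sum(a$risk_category == "not_reported"), n_all),
    cat_row("advice_stop_smoking", adv[["stop_smoking"]], n_all),
    cat_row("advice_lose_weight", adv[["lose_weight"]], n_all),
    cat_row("advice_more_exercise", adv[["more_exercise"]], n_all),
    cat_row("advice_new_medication", adv[["new_medication"]], n_all)
  )
}

#' Monitoring chart in failure-count space
#'
#' Draws the cumulative failures against evaluable patients (the events
#' line), with the unsafe boundary in red and the safe boundary in green, the
#' scale on which the program's stopping rule is monitored.
#'
#' @param object An `sc_monitoring` result.
#' @param ... Unused.
#' @return A ggplot object.
#' @importFrom ggplot2 autoplot
#' @export autoplot
#' @export
autoplot.sc_monitoring <- function(object, ...) {
  tr <- trajectory_series(object)
  ggplot2::ggplot(tr, ggplot2::aes(x = .data$n_evaluable)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fail_bound_unsafe),
                       color = "red") +
    ggplot2::geom_line(ggplot2::aes(y = .data$fail_bound_safe),
                       color = "darkgreen") +
    ggplot2::geom_step(ggplot2::aes(y = .data$n_failures), color = "blue") +
    ggplot2::labs(x = "Evaluable patients",
                  y = "Cumulative failures",
                  title = "Sequential stopping rule",
                  subtitle = sprintf("verdict: %s", object$verdict)) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.sc_monitoring
#' @param result An `sc_monitoring` result.
#' @export
plot_monitoring <- function(result, ...) autoplot.sc_monitoring(result, ...)
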