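#' Specify a sequential safety-monitoring design
#'
#' Defines the hypothesis pair and error rates of a fully sequential test of
#' a per-patient failure probability, as used to monitor failures in relapse
#' detection during shared-care follow-up. The test contrasts an acceptable
#' failure rate `p_acceptable` (null) against a maximum-tolerated rate
#' `p_unacceptable`, truncating once `horizon_n` evaluable patients have
#' contributed an outcome.
#'
#' The defaults encode the shared-care study conditions: acceptable failure
#' rate 5%, maximum tolerated 10%, one-sided significance 0.05, 80% power,
#' 225 evaluable patients, and a 10% non-evaluable rate used when inflating
#' enrollment.
#'
#' @param p_acceptable Acceptable per-patient failure probability (null).
#' @param p_unacceptable Maximum-tolerated failure probability (alternative).
#' @param alpha_total One-sided significance level: the maximum probability
#'   of a *safe* conclusion when the true rate equals `p_unacceptable`.
#' @param power_target Target probability of a safe conclusion when the true
#'   rate equals `p_acceptable`.
#' @param horizon_n Number of evaluable patients at which the test truncates.
#' @param nonevaluable_rate Expected fraction of enrolled patients who never
#'   contribute an evaluable outcome; used by [required_sample_size()].
#' @return An object of class `sc_design`.
#' @seealso [wald_boundaries()], [sc_calibrate()], [operating_characteristics()]
#' @examples
#' sc_design()
#' sc_design(horizon_n = 250)
#' @export
sc_design <- function(p_acceptable = 0.05,
                      p_unacceptable = 0.10,
                      alpha_total = 0.05,
                      power_target = 0.80,
                      horizon_n = 225,
                      nonevaluable_rate = 0.10) {
  check_prob(p_acceptable, "p_acceptable")
  check_prob(p_unacceptable, "p_unacceptable")
  check_prob(alpha_total, "alpha_total")
  check_prob(power_target, "power_target")
  check_prob(nonevaluable_rate, "nonevaluable_rate", open = FALSE)
  if (p_acceptable >= p_unacceptable) {
    abort_sc("`p_acceptable` must be strictly less than `p_unacceptable`.",
             "invalid_design")
  }
  if (power_target <= 0.5) {
    abort_sc("`power_target` must exceed 0.5.", "invalid_design")
  }
  if (!is.numeric(horizon_n) || length(horizon_n) != 1L ||
      horizon_n < 1 || horizon_n != floor(horizon_n)) {
    abort_sc("`horizon_n` must be a positive integer.", "invalid_design")
  }
  structure(
    list(p_acceptable = p_acceptable,
         p_unacceptable = p_unacceptable,
         alpha_total = alpha_total,
         power_target = power_target,
         horizon_n = as.integer(horizon_n),
         nonevaluable_rate = nonevaluable_rate),
    class = "sc_design"
  )
}

#' @export
print.sc_design <- function(x, ...) {
  cat("<sc_design>\n")
  cat(sprintf("  H0: p = %.3g (acceptable)  vs  H1: p = %.3g (unacceptable)\n",
              x$p_acceptable, x$p_unacceptable))
  cat(sprintf("  one-sided alpha %.3g, power target %.3g\n",
              x$alpha_total, x$power_target))
  cat(sprintf("  truncation horizon %d evaluable patients, non-evaluable rate %.3g\n",
              x$horizon_n, x$nonevaluable_rate))
  invisible(x)
}

#' Log-likelihood-ratio increment of one evaluable outcome
#'
#' The fully sequential test accumulates, per evaluable patient, the
#' log-likelihood ratio of the maximum-tolerated failure rate against the
#' acceptable rate: `log(p1/p0)` for a failure and `log((1 - p1)/(1 - p0))`
#' for a success.
#'
#' @param outcome Character vector of `"failure"`/`"success"`.
#' @param design An [sc_design()].
#' @return Numeric vector of increments.
#' @examples
#' llr_increment("failure", sc_design())  # log 2
#' @export
llr_increment <- function(outcome, design = sc_design()) {
  stopifnot(inherits(design, "sc_design"))
  bad <- !outcome %in% c("failure", "success")
  if (any(bad)) {
    abort_sc(sprintf("invalid outcome label(s): %s",
                     paste(unique(outcome[bad]), collapse = ", ")),
             "invalid_outcome")
  }
  p0 <- design$p_acceptable
  p1 <- design$p_unacceptable
  ifelse(outcome == "failure", log(p1 / p0), log((1 - p1) / (1 - p0)))
}

new_boundary <- function(log_lower, log_upper, design, calibration = NULL) {
  if (!(log_lower < 0 && 0 < log_upper)) {
    abort_sc("degenerate boundaries: need log_lower < 0 < log_upper.",
             "degenerate_boundary")
  }
  structure(
    list(log_upper = log_upper,
         log_lower = log_lower,
         llr_failure = llr_increment("failure", design),
         llr_success = llr_increment("success", design),
         design = design,
         calibrated = !is.null(calibration),
         calibration = calibration),
    class = "sc_boundary"
  )
}

#' Wald stopping boundaries
#'
#' Classical sequential probability-ratio thresholds
#' `log_upper = log((1 - beta)/alpha)` (conclude *unsafe* at or above) and
#' `log_lower = log(beta/(1 - alpha))` (conclude *safe* at or below), with
#' `alpha = alpha_total` and `beta = 1 - power_target`. These ignore the
#' truncation at `horizon_n`; use [sc_calibrate()] to enforce the design's
#' error rates under truncation.
#'
#' @param design An [sc_design()].
#' @return An object of class `sc_boundary` (uncalibrated).
#' @examples
#' wald_boundaries(sc_design())  # log 16 and log(0.2/0.95)
#' @export
wald_boundaries <- function(design = sc_design()) {
  stopifnot(inherits(design, "sc_design"))
  alpha <- design$alpha_total
  beta <- 1 - design$power_target
  new_boundary(log_lower = log(beta / (1 - alpha)),
               log_upper = log((1 - beta) / alpha),
               design = design)
}

#' @export
print.sc_boundary <- function(x, ...) {
  cat("<sc_boundary>\n")
  cat(sprintf("  safe (lower) threshold %8.4f   unsafe (upper) threshold %8.4f\n",
              x$log_lower, x$log_upper))
  cat(sprintf("  increments: failure %+.4f, success %+.4f\n",
              x$llr_failure, x$llr_success))
  if (x$calibrated) {
    cal <- x$calibration
    cat(sprintf("  calibrated at horizon %d (%d sims, seed %s): realized alpha %.4f, power %.4f%s\n",
                x$design$horizon_n, cal$n_sims, format(cal$seed),
                cal$realized_alpha, cal$realized_power,
                if (isTRUE(cal$feasible)) "" else "  [power target NOT met]"))
  } else {
    cat("  uncalibrated (Wald form; truncation ignored)\n")
  }
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.sc_boundary <- function(x, ...) {
  tibble::tibble(
    log_lower = x$log_lower,
    log_upper = x$log_upper,
    llr_failure = x$llr_failure,
    llr_success = x$llr_success,
    calibrated = x$calibrated,
    realized_alpha = if (x$calibrated) x$calibration$realized_alpha else NA_real_,
    realized_power = if (x$calibrated) x$calibration$realized_power else NA_real_
  )
}

#' Fresh sequential-test state
#'
#' @param design An [sc_design()] (kept for reference by [sc_step()]).
#' @return An object of class `sc_state` with zero evaluable patients, an
#'   empty trajectory and status `"continue"`.
#' @export
sc_state <- function(design = sc_design()) {
  structure(
    list(n_evaluable = 0L,
         n_failures = 0L,
         cum_llr = 0,
         status = "continue",
         design = design,
         trajectory = tibble::tibble(n_evaluable = integer(),
                                     n_failures = integer(),
                                     cum_llr = double())),
    class = "sc_state"
  )
}

#' @export
print.sc_state <- function(x, ...) {
  cat(sprintf("<sc_state> n = %d, failures = %d, cum LLR = %.4f, status = %s\n",
              x$n_evaluable, x$n_failures, x$cum_llr, x$status))
  invisible(x)
}

#' Advance the sequential test by one evaluable outcome
#'
#' Adds one outcome's log-likelihood-ratio increment to the state and checks
#' the stopping boundaries. Crossing is inclusive and the unsafe check takes
#' precedence: status becomes `"unsafe"` when the cumulative statistic is at
#' or above `log_upper`, else `"safe"` at or below `log_lower`, else
#' `"continue"`. Terminal states cannot be stepped.
#'
#' @param state An [sc_state()] with status `"continue"`.
#' @param outcome `"failure"` or `"success"`.
#' @param boundary An `sc_boundary`.
#' @return The updated `sc_state`, trajectory extended by one row.
#' @examples
#' st <- sc_state()
#' b <- wald_boundaries()
#' st <- sc_step(st, "success", b)
#' st$status
#' @export
sc_step <- function(state, outcome, boundary) {
  stopifnot(inherits(state, "sc_state"), inherits(boundary, "sc_boundary"))
  if (state$status != "continue") {
    abort_sc(sprintf("cannot step a terminal state (status = %s).", state$status),
             "terminal_state")
  }
  inc <- if (identical(outcome, "failure")) {
    boundary$llr_failure
  } else if (identical(outcome, "success")) {
    boundary$llr_success
  } else {
    abort_sc(sprintf("invalid outcome label: %s", format(outcome)),
             "invalid_outcome")
  }
  state$n_evaluable <- state$n_evaluable + 1L
  state$n_failures <- state$n_failures + as.integer(outcome == "failure")
  state$cum_llr <- state$cum_llr + inc
  state$status <- if (state$cum_llr >= boundary$log_upper) {
    "unsafe"
  } else if (state$cum_llr <= boundary$log_lower) {
    "safe"
  } else {
    "continue"
  }
  state$trajectory <- dplyr::bind_rows(
    state$trajectory,
    tibble::tibble(n_evaluable = state$n_evaluable,
                   n_failures = state$n_failures,
                   cum_llr = state$cum_llr)
  )
  state
}

## ---- vectorized simulation machinery ------------------------------------

# n_sims x horizon matrix of cumulative LLR paths under Bernoulli(p)
sim_llr_paths <- function(horizon, p, n_sims, llr_failure, llr_success, seed) {
  set.seed(as.integer(seed %% 2147483647))
  fail <- matrix(stats::runif(n_sims * horizon) < p, n_sims, horizon)
  cum <- ifelse(fail, llr_failure, llr_success)
  for (j in seq_len(horizon)[-1]) cum[, j] <- cum[, j - 1L] + cum[, j]
  cum
}

first_true <- function(m) {
  # first TRUE column index per row; Inf if none
  idx <- max.col(m, ties.method = "first")
  hit <- m[cbind(seq_len(nrow(m)), idx)]
  out <- rep(Inf, nrow(m))
  out[hit] <- idx[hit]
  out
}

# verdict per simulated path given thresholds; unsafe checked first at ties
# (a path cannot touch both boundaries at the same step, but the convention
# is kept explicit)
crossing_probs <- function(cum, log_lower, log_upper) {
  iu <- first_true(cum >= log_upper)
  il <- first_true(cum <= log_lower)
  unsafe <- is.finite(iu) & (iu <= il)
  safe <- is.finite(il) & (il < iu)
  n_at <- pmin(iu, il)
  n_at[!is.finite(n_at)] <- ncol(cum)
  list(prob_safe = mean(safe),
       prob_unsafe = mean(unsafe),
       prob_undecided = mean(!safe & !unsafe),
       mean_n_at_decision = mean(n_at))
}

#' Operating characteristics of a stopping boundary by simulation
#'
#' Simulates `n_sims` cohorts of `design$horizon_n` independent
#' Bernoulli(`true_p`) evaluable outcomes, streams each through the
#' sequential test, and estimates the probabilities of a safe crossing, an
#' unsafe crossing and of reaching the truncation horizon undecided, together
#' with the mean number of evaluable outcomes at the decision (undecided
#' cohorts count at the horizon).
#'
#' @param design An [sc_design()].
#' @param boundary An `sc_boundary`.
#' @param true_p True per-patient failure probability to simulate under.
#' @param n_sims Number of simulated cohorts.
#' @param seed Integer seed; identical seeds give identical results.
#' @return A one-row tibble with columns `true_p`, `prob_safe`,
#'   `prob_unsafe`, `prob_undecided`, `mean_n_at_decision`, `n_sims`.
#' @examples
#' operating_characteristics(sc_design(horizon_n = 60), wald_boundaries(),
#'                           true_p = 0, n_sims = 10, seed = 1)
#' @export
operating_characteristics <- function(design, boundary, true_p, n_sims, seed) {
  stopifnot(inherits(design, "sc_design"), inherits(boundary, "sc_boundary"))
  check_prob(true_p, "true_p", open = FALSE)
  if (n_sims < 1) abort_sc("`n_sims` must be at least 1.", "invalid_design")
  cum <- sim_llr_paths(design$horizon_n, true_p, n_sims,
                       boundary$llr_failure, boundary$llr_success, seed)
  pr <- crossing_probs(cum, boundary$log_lower, boundary$log_upper)
  tibble::tibble(true_p = true_p,
                 prob_safe = pr$prob_safe,
                 prob_unsafe = pr$prob_unsafe,
                 prob_undecided = pr$prob_undecided,
                 mean_n_at_decision = pr$mean_n_at_decision,
                 n_sims = as.integer(n_sims))
}

#' Calibrate the safe threshold to the design's error rates under truncation
#'
#' Wald thresholds ignore truncation: under a hard horizon the probability of
#' ever crossing the safe (lower) threshold when the true failure rate equals
#' `p_unacceptable` exceeds the nominal level. `sc_calibrate()` keeps the
#' Wald unsafe (upper) threshold and rescales the safe threshold by a
#' bisection search on simulated cohorts so that the estimated probability of
#' a safe conclusion under `p_unacceptable` is as large as possible while not
#' exceeding `alpha_total`; the realized power (probability of a safe
#' conclusion under `p_acceptable`, estimated on an independent set of
#' simulated cohorts) is then recorded.
#'
#' If the realized power falls short of `power_target`, no threshold pair can
#' meet both constraints at this horizon (power is monotone in the threshold
#' once the alpha constraint binds). With `on_infeasible = "error"` (default)
#' a named error advises a larger horizon; with `"warn"` the
#' maximum-power boundary is returned with `calibration$feasible = FALSE`.
#'
#' @param design An [sc_design()].
#' @param n_sims Simulated cohorts per hypothesis; at least 6400 so the
#'   Monte-Carlo standard error of the estimated error probabilities is
#'   below 0.005.
#' @param seed Integer seed (two independent child streams are derived).
#' @param on_infeasible `"error"` or `"warn"`.
#' @return A calibrated `sc_boundary` with `calibration` metadata:
#'   `n_sims`, `seed`, `scale`, `realized_alpha`, `realized_power`,
#'   `feasible`.
#' @examples
#' \donttest{
#' b <- sc_calibrate(sc_design(horizon_n = 240), n_sims = 6400, seed = 7)
#' tidy(b)
#' }
#' @export
sc_calibrate <- function(design, n_sims = 10000, seed = 1,
                         on_infeasible = c("error", "warn")) {
  stopifnot(inherits(design, "sc_design"))
  on_infeasible <- match.arg(on_infeasible)
  if (n_sims < 6400) {
    abort_sc(paste0("`n_sims` must be at least 6400 so the Monte-Carlo ",
                    "standard error of the error probabilities stays below 0.005."),
             "invalid_design")
  }
  wald <- wald_boundaries(design)
  seeds <- child_seeds(seed, 2)
  cum1 <- sim_llr_paths(design$horizon_n, design$p_unacceptable, n_sims,
                        wald$llr_failure, wald$llr_success, seeds[1])
  cum0 <- sim_llr_paths(design$horizon_n, design$p_acceptable, n_sims,
                        wald$llr_failure, wald$llr_success, seeds[2])
  alpha_at <- function(scale) {
    crossing_probs(cum1, scale * wald$log_lower, wald$log_upper)$prob_safe
  }
  # prob_safe under p_unacceptable is nonincreasing in the scale; find the
  # smallest scale meeting the alpha constraint (maximizes power)
  lo <- 1e-3
  hi <- 1
  while (alpha_at(hi) > design$alpha_total && hi < 64) hi <- hi * 2
  if (alpha_at(hi) > design$alpha_total) {
    abort_sc("no safe threshold meets the alpha constraint at this horizon.",
             "infeasible_design")
  }
  if (alpha_at(lo) <= design$alpha_total) {
    hi <- lo
  } else {
    for (i in 1:50) {
      mid <- (lo + hi) / 2
      if (alpha_at(mid) <= design$alpha_total) hi <- mid else lo <- mid
    }
  }
  scale <- hi
  log_lower <- scale * wald$log_lower
  realized_alpha <- alpha_at(scale)
  realized_power <- crossing_probs(cum0, log_lower, wald$log_upper)$prob_safe
  feasible <- realized_power >= design$power_target
  if (!feasible) {
    msg <- sprintf(paste0("calibrated boundary attains power %.4f < target %.3g ",
                          "at horizon %d (alpha constraint binding at %.4f); ",
                          "a larger horizon is required for a feasible design."),
                   realized_power, design$power_target, design$horizon_n,
                   realized_alpha)
    if (on_infeasible == "error") abort_sc(msg, "infeasible_design")
    rlang::warn(msg, class = "sharedcare_infeasible_design_warning")
  }
  new_boundary(log_lower = log_lower,
               log_upper = wald$log_upper,
               design = design,
               calibration = list(n_sims = as.integer(n_sims),
                                  seed = seed,
                                  scale = scale,
                                  realized_alpha = realized_alpha,
                                  realized_power = realized_power,
                                  feasible = feasible))
}

#' Required evaluable and enrolled sample size
#'
#' Binary search for the smallest truncation horizon at which
#' [sc_calibrate()] is feasible, i.e. simulated power reaches `power_target`
#' while the safe-conclusion probability under `p_unacceptable` stays at or
#' below `alpha_total`. Enrollment is inflated by the non-evaluable rate with
#' ceiling division. A fixed-sample normal-approximation size for the same
#' one-sided two-proportion contrast is reported alongside for reference; the
#' truncated sequential size is not constrained by it.
#'
#' @param design An [sc_design()] (its `horizon_n` is ignored by the search).
#' @param n_sims Simulated cohorts per feasibility check (>= 6400).
#' @param seed Integer seed.
#' @param max_horizon Upper end of the search range.
#' @return A list with `n_evaluable`, `n_enrolled`, `fixed_sample_n` and the
#'   calibrated boundary at `n_evaluable`.
#' @examples
#' \donttest{
#' required_sample_size(sc_design(), n_sims = 6400, seed = 11)
#' }
#' @export
required_sample_size <- function(design, n_sims = 10000, seed = 1,
                                 max_horizon = 600) {
  stopifnot(inherits(design, "sc_design"))
  feasible_at <- function(h) {
    d <- sc_design(design$p_acceptable, design$p_unacceptable,
                   design$alpha_total, design$power_target,
                   horizon_n = h, nonevaluable_rate = design$nonevaluable_rate)
    b <- tryCatch(
      suppressWarnings(sc_calibrate(d, n_sims = n_sims, seed = seed,
                                    on_infeasible = "warn")),
      sharedcare_infeasible_design = function(e) NULL
    )
    if (is.null(b) || !isTRUE(b$calibration$feasible)) NULL else b
  }
  lo <- 1L
  hi <- as.integer(max_horizon)
  b_hi <- feasible_at(hi)
  if (is.null(b_hi)) {
    abort_sc(sprintf("design infeasible even at horizon %d.", hi),
             "infeasible_design")
  }
  while (hi - lo > 1L) {
    mid <- as.integer((lo + hi) %/% 2)
    b_mid <- feasible_at(mid)
    if (is.null(b_mid)) lo <- mid else { hi <- mid; b_hi <- b_mid }
  }
  p0 <- design$p_acceptable
  p1 <- design$p_unacceptable
  fixed_n <- ((stats::qnorm(1 - design$alpha_total) * sqrt(p0 * (1 - p0)) +
               stats::qnorm(design$power_target) * sqrt(p1 * (1 - p1))) /
              (p1 - p0))^2
  list(n_evaluable = hi,
       n_enrolled = as.integer(ceiling(hi / (1 - design$nonevaluable_rate))),
       fixed_sample_n = fixed_n,
       boundary = b_hi)
}
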