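---
title: "Sequential safety monitoring of shared-care cancer follow-up"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sequential safety monitoring of shared-care cancer follow-up}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sharedcare)
```

## The problem

When part of a cancer survivor's follow-up is moved from the oncology
clinic to the primary care physician (PCP), the central safety question is
whether signals of relapse are still detected and acted on in time. The
`sharedcare` package implements the statistical machinery used to answer
that question for a shared-care program in testicular cancer survivorship:

* a **fully sequential stopping rule** for per-patient detection failures,
  with calibration, operating characteristics and sample-size search;
* **failure adjudication** rules applied to a visit ledger, reducing each
  patient to one evaluable Bernoulli outcome;
* the **SCORE** 10-year cardiovascular risk model with a +15-year survivor
  age adjustment, risk categories and an NCEP-ATP III metabolic-syndrome
  classifier;
* **HADS-A** and **RAND-36** questionnaire scoring with longitudinal
  comparison;
* a **synthetic cohort generator** so every component is testable without
  patient data.

## The sequential test

Each evaluable patient contributes one Bernoulli outcome: *failure* (a
relapse signal missed or not acted on within two weeks, realized at the
first failing visit) or *success* (two years of shared-care follow-up
completed with at least two primary-care visits and no failure). Patients
leaving the program early for other reasons are censored and contribute
nothing.

The test contrasts an acceptable failure probability $p_0 = 0.05$ against a
maximum-tolerated $p_1 = 0.10$. After each outcome the cumulative
log-likelihood ratio is updated by

$$\lambda_\text{failure} = \log\frac{p_1}{p_0} = \log 2, \qquad
  \lambda_\text{success} = \log\frac{1-p_1}{1-p_0} = \log\frac{0.90}{0.95},$$

and the cumulative sum $\Lambda_n$ is compared with two thresholds: at or
above the *unsafe* threshold the program is flagged (the monitoring
committee is alerted), at or below the *safe* threshold the failure rate is
concluded to be acceptably low. Crossings are inclusive and the unsafe
check takes precedence — a deliberate, conservative tie rule: four
consecutive failures give $4\log 2 = \log 16$, exactly the Wald unsafe
threshold, and are treated as a crossing.

The classical Wald thresholds are
$\log\frac{1-\beta}{\alpha} = \log 16$ and
$\log\frac{\beta}{1-\alpha} = \log\frac{0.20}{0.95}$ for
$\alpha = 0.05,\ \beta = 0.20$. These ignore the design's hard truncation
at a horizon of 225 evaluable patients. Under truncation the probability of
*ever* crossing the safe threshold when the true rate is $p_1$ is well
above the nominal level, so `sc_calibrate()` rescales the safe threshold by
a bisection search on simulated cohorts until the estimated probability of
a safe conclusion under $p_1$ is as high as possible while not exceeding
$\alpha$; the realized power under $p_0$ is then measured on an independent
simulation stream and recorded in the boundary's calibration metadata. The
unsafe threshold is kept at its Wald value: the calibration contract
concerns safe crossings only, and the attainable power is essentially
insensitive to the upper threshold (checked over upper thresholds from 1.4
to effectively infinite).

### Why the 80% power target is not attainable at horizon 225

An exact dynamic program over the (patients, failures) lattice shows that
at a truncation horizon of 225 evaluable outcomes the *maximum* attainable
probability of a safe conclusion under $p_0 = 0.05$, subject to keeping the
probability of a safe conclusion under $p_1 = 0.10$ at or below 0.05, is
about 0.789 with the Wald unsafe threshold (0.791 as the upper threshold
grows without bound) — for *every* threshold pair. The smallest horizon at
which both constraints hold simultaneously is 231 evaluable patients
(power 0.808). A design that additionally acted at the truncation point
(accepting safety when the statistic is merely *near* the safe threshold at
patient 225) could close the gap, but this package deliberately reports an
uncrossed horizon as *undecided* rather than coercing a verdict, because
the monitoring rule only ever acts on crossings.

`sc_calibrate()` therefore returns, at horizon 225, the maximum-power
boundary meeting the alpha constraint, flags `feasible = FALSE`, and either
warns or errors ("a larger horizon is required") depending on
`on_infeasible`. The package's acceptance checks report the realized power
honestly (about 79%) rather than tuning the simulation toward the target.
`required_sample_size()` runs the feasibility search and lands near 231
evaluable patients; with the design's 10% non-evaluable rate and ceiling
inflation this gives about 257 enrolled. The fixed-sample
normal-approximation size for the same one-sided contrast is about 150,
reported alongside for reference only — a truncated sequential design needs
more patients than a fixed-sample test because most of its sample paths
must travel far below zero before the (deliberately strict) safe threshold
is reached.

### Verdict and trajectory

`run_monitoring()` orders the evaluable outcomes by realization date
(success at the end of the 2-year window, failure at the first failing
visit; ties broken by patient identifier), streams them through the rule,
and stops at the first crossing. The retained trajectory converts to a
monitoring chart with `autoplot()`: cumulative failures in blue against the
red (unsafe) and green (safe) boundary lines, both expressed in
failure-count space via $f(n) = (c - n\lambda_\text{success}) /
(\lambda_\text{failure} - \lambda_\text{success})$ for threshold $c$.

The worked example `example_cohort_ledger()` fixes a calendar ordering in
which the four failing visits are interleaved among the completers'
outcomes (2015–2017). The ordering matters in principle: a hypothetical
stream opening with all four failures back-to-back would touch the unsafe
threshold exactly. The shipped example documents its ordering; the verdict
is reported for that ordering, not claimed to be permutation-free.

## Failure adjudication

A visit is a failure when, and only when, one of three things happened:

1. an abnormal finding without appropriate action within 14 days
   (*"within two weeks"* is read as an inclusive lag of at most 14 calendar
   days — the re-test day counts);
2. a missed appointment where the patient could not be contacted within 14
   days;
3. a wrong tumor-marker panel (the correct panel is AFP, β-hCG and LDH)
   that the monitoring case manager did not notice. A *caught* wrong panel
   is not a failure — the harm model is the undetected gap in relapse-risk
   assessment.

Everything else is logistics, not safety: an elevated LDH attributed to
hemolysis during sample transport and re-tested within two weeks, a report
returned late to the coordinating center, a timely referral after an
abnormal physical exam, or a relapse detected and acted on in time. One
patient contributes at most one outcome to the sequential stream (the
power calculation is per patient), while per-visit failure counts are
reported separately so the visit-level bookkeeping stays reproducible.

Patients whose shared-care follow-up ends early — dropout by preference,
or a relapse (which moves the patient back to hospital-only care) — are
censored unless a failing visit preceded the exit. Treating detected
relapse as censoring rather than success keeps the evaluable unit exactly
as the power calculation defines it: completion of the 2-year window, or
failure.

## Cardiovascular risk

`score_risk()` implements the SCORE low-risk-region Weibull equations
(coronary and non-coronary components summed, total-cholesterol variant):
for each cause, baseline survival $S_0(a) = \exp(-e^{\alpha}(a-20)^p)$,
proportional risk factors
$w = \beta_1(\text{chol}-6) + \beta_2(\text{SBP}-120) +
\beta_3\,\text{smoker}$, and 10-year risk
$1 - S(a{+}10)/S(a)$ with $S = S_0^{e^w}$. The equations (rather than the
chart form) were chosen for testability: they are monotone in every risk
factor, which the test suite verifies on a grid. The output is the
mortality-based SCORE risk and is labelled as such; whether the original
program's PCPs used a morbidity-inflated variant is not recoverable, so no
multiplier is applied.

The survivor adjustment adds 15 years to the actual age before evaluation
(`adjusted_age()`), reflecting the accelerated cardiovascular ageing seen
after platinum-based chemotherapy. Adjusted ages frequently exceed the
model's validity window (age 20–65; SBP 100–180 mmHg; cholesterol
3–8 mmol/l); inputs are clipped to the window with a warning rather than
extrapolated. Risk categories are left-closed — $[0,10)$ low, $[10,20)$
mid, $\ge 20\%$ high — matching the reporting convention "≥20%"; an
assessment with a missing input becomes `not_reported` instead of failing
the pipeline, mirroring the real program's 28% unreported conclusions.

Metabolic syndrome uses the male NCEP-ATP III criteria (waist > 102 cm,
triglycerides ≥ 1.7 mmol/l, HDL < 1.03 mmol/l, BP ≥ 130/85 or treatment,
glucose ≥ 5.6 mmol/l or treatment; three of five required). The cohort is
male, and the program cites no explicit definition, so this is a documented
assumption. Any missing criterion input makes the classification
indeterminate and shrinks the prevalence denominator, which is why
prevalences are reported as n/denominator pairs. Advice mapping
(`advise()`) is a minimal, explicitly configurable rule set consistent with
the program's reported advice frequencies; it does not claim to reproduce
guideline text.

## Questionnaires

HADS-A is the sum of seven 0–3 items (0–21) with the instrument's
conventional anxiety cutoff of ≥ 8 (the program reports a flagged
percentage but no cutoff; 8 is the standard choice). RAND-36 uses the
published two-step scoring: recode each item to 0–100 by the RAND key,
then average non-missing items within each of the eight subscales. No
imputation anywhere — missing items make a score undefined, matching the
reduced denominators of the real data. `longitudinal_compare()` pairs
administrations by patient and applies a paired two-sided t-test (the
program does not name its test; a Wilcoxon signed-rank option is provided).
Two conventions are documented: identical administrations give p = 1 (no
evidence of change), and an exactly constant nonzero shift gives p = 0.

## The synthetic cohort generator

`cohort_config()` holds every generator target; defaults are the study
conditions, and no target is hard-coded in any assertion. The schedule
template places primary-care visits at months 3, 9, 15, 21 and oncology
visits at 6, 12, 18, 24 (CT at 6, 12, 24): the program's fixed imaging
months are published, the exact cadence between them is not, so the
template is configurable and guarantees at least two primary-care visits
within the 2-year horizon.

Failures are assigned per evaluable patient at `p_failure` (default the
program-observed 4/113; the design rates 0.05/0.10 are the values to simulate
under when studying the stopping rule), realized at a random primary-care
visit as either an uncontactable missed appointment or an undetected
wrong-marker panel, mixed by the two observed per-visit rates (3 : 1).
Assigning failures among patients who neither drop out nor relapse makes
the evaluable failure fraction recover `p_failure` exactly in expectation,
which the test suite checks at 1,000 patients across several rates. Benign
incidents (hemolysis re-tests at 26/364 per visit, late reports at 81/364,
same-day returns at 73/364, rare timely referrals) are drawn per visit.

Continuous measurements are drawn from unimodal families chosen for
positivity and skew — log-normal for lipids, glucose, age and BMI,
truncated normal for pressures and waist — and parameterized from the
reported (median, range) pairs by a range-matching recipe: with
$z = \Phi^{-1}(1 - 1/(2 n_\text{ref}))$ and $n_\text{ref} = 140$
assessments, the expected extremes of a sample sit near the median
$\pm z$ standard deviations, so $\sigma = (\text{hi}-\text{lo})/2z$ (or
$\sigma_{\log} = \log(\text{hi}/\text{lo})/2z$). Medians are pinned by
construction; variances are honest guesses constrained by the printed
ranges, since no dispersion statistics are published. Total cholesterol is
not tabulated at all and is synthesized log-normal with median 5.0 mmol/l.

HADS-A items follow a patient-level beta-binomial: a latent propensity
$p \sim \text{Beta}(a, b)$ with $(a, b)$ solved at run time so the 7-item
sum has mean 3.2 and $P(\text{sum} \ge 8) = 6.4\%$; items are then
Binomial(3, $p$). Follow-up administrations reuse the latent propensity
(pairing) shifted by `hads_shift`/21, so the default zero shift reproduces
the baseline distribution, emulating the program's stable anxiety levels.

What the generator does *not* emulate: relapse biology and marker
kinetics, correlations between cardiovascular measurements (they are drawn
independently), seasonal or site effects in visit timing, and
informative dropout. Tests passing on synthetic cohorts therefore
demonstrate the correctness of the statistical machinery under the stated
sampling model, not the clinical properties of any real population.

## Numerical choices and problem sizes

* Calibration requires at least 6,400 simulated cohorts per hypothesis
  (Monte-Carlo standard error of an error probability below 0.005);
  the package's own checks use 6,400–10,000.
* The bisection for the safe-threshold scale reuses one fixed set of
  simulated paths per hypothesis (common random numbers), so the search is
  deterministic given the seed and costs seconds.
* The exhaustive-enumeration oracle (all $2^h$ weighted outcome sequences)
  cross-checks the simulation at horizons up to 12.
* Every stochastic operation takes an explicit integer seed; identical
  seeds give bit-identical results, including whole generated ledgers.
* The sample-size search brackets the smallest feasible horizon by binary
  search over calibrations; with 6,400 simulations it reproducibly lands
  within a few patients of the exact value 231.

## Worked example

```{r example, eval = FALSE}
design <- sc_design(horizon_n = 225)
boundary <- sc_calibrate(design, n_sims = 10000, seed = 1,
                         on_infeasible = "warn")

ledger <- example_cohort_ledger()
result <- run_monitoring(ledger, design, boundary)
glance(result)
autoplot(result)

assessments <- assess_cvrm(example_cvrm_measurements())
summarize_cvrm(assessments)
```

## Known limitations

* The original program's appendix construction ("a constant value of α")
  is not published in the main text; this package's truncated, calibrated
  Wald rule matches the *printed* operating characteristics, not
  necessarily the original arithmetic. Its 225/245 sample sizes are treated
  as soft reference points (the package computes 231 evaluable / 257
  enrolled; the printed 245 does not equal ceiling inflation of 225, whose
  arithmetic is not recoverable).
* SCORE is evaluated outside its validated age range for older adjusted
  ages only by clipping, which underestimates risk beyond 65.
* The advice mapping and the metabolic-syndrome definition are documented
  package choices, not transcriptions of the national guideline.
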