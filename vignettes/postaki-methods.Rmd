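---
title: "Methods: validating and acting on post-AKI risk models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: validating and acting on post-AKI risk models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(postaki)
```

# The problem

Hospital survivors who had acute kidney injury (AKI) face two distinct
follow-up questions: who should a *nonspecialist* see early to preempt death
or unplanned readmission within 90 days of discharge, and which AKI
survivors should a *nephrologist* follow because they are likely to progress
to CKD G4–G5 (eGFR < 30 mL/min/1.73 m²) within a year. Two published
logistic models answer these questions; `postaki` implements the machinery
needed to judge whether acting on them in a new population does more good
than harm: external validation, updating, decision curve analysis, the
KDIGO-based AKI ascertainment that defines their key predictor, care-pathway
process mining, and a synthetic-data layer that makes the whole pipeline
exercisable without access to any health-records data.

# Models as data

A `model_spec` holds the intercept and the coded terms of a logistic model.
Coefficients of the packaged models are the natural logs of the *published*
odds ratios at printed precision; no attempt is made to recover unrounded
derivation coefficients, because only the odds ratios are public. Codings
follow the published footnotes: baseline eGFR enters the readmissions model
as linear plus quadratic terms in eGFR/10; baseline creatinine enters the
CKD model per 0.1 mg/dL; prior admissions is a per-admission count;
categorical predictors (AKI stage, discharge creatinine category,
albuminuria) declare a full level set with a reference level at coefficient
zero. "Unmeasured" albuminuria is a genuine category — in routine data, not
having an albuminuria measurement is informative — and is never treated as
missingness. Continuous predictors are not centered, so absolute risks are
auditable directly against the published intercepts.

Two printed values deserve flags rather than silent repair:

* The CKD model's discharge-creatinine reference category is printed as
  "<0.1 mg/dL"; we treat this as a typographical error for "<1.0 mg/dL",
  consistent with the cohort characteristic tables that use <1.0.
* The readmissions model's age odds ratio is printed as 1.17 *per year*,
  which is implausibly large for a 1-year unit (it implies odds doubling
  every ~4.4 years and predicted risks saturating near 1 for typical adult
  ages). It is implemented exactly as printed and flagged in the model's
  `notes`; users of the as-printed model should interpret its absolute risks
  accordingly. This choice propagates into the simulation design below.

Specs serialize to JSON (17 significant digits, so predictions survive the
round trip bit-exactly) and users can add models under the same schema.

# AKI detection and staging

`detect_aki_grampian()` implements the KDIGO-based flagging used by the
readmissions model: for every in-admission creatinine, (1) a rise of more
than 0.3 mg/dL above the lowest value within 48 hours, (2) a 50% rise over
the lowest value in the past 7 days, or (3) a 50% rise over the *median* of
the 8–90 day window, falling back to the 91–365 day median only when the
closer window has no samples at all (and skipping the criterion, without
error, when both are empty). `detect_aki_alberta()` implements the CKD
model's variant — a >0.3 mg/dL or >50% rise during hospitalization over the
most recent *outpatient* baseline 7–365 days before admission — and returns
an explicit *indeterminate* result (flag `NA`) when no qualifying baseline
exists, which is deliberately distinct from "no AKI".

The publications say only "KDIGO-based", so severity staging is a
configurable convention, defaulting to the usual KDIGO multipliers: stage 1
when a criterion fires, stage 2 at ≥ 2.0× the firing criterion's reference
value, stage 3 at ≥ 3.0× or an absolute 4.0 mg/dL. When several criteria
fire, the one yielding the highest stage is reported, ties broken in the
listed order. Windows are anchored at each index time t: `[t−2, t)`,
`[t−7, t)`, `[t−90, t−8]`, `[t−365, t−91]` days. Urine-output criteria and
dialysis-based staging are out of scope.

Related preprocessing: `ckd_epi_egfr()` is the CKD-EPI 2009 creatinine
equation with the race coefficient configurable and **off** by default
(UK laboratory practice in the study era applied the non-Black coefficient
universally); `ascertain_ckd_g45()` requires two outpatient eGFR values
below 30 at least 3 months apart — operationalized as ≥ 90 days, since the
source does not state 90 vs 91/92 days — inside a window that is half-open
at cohort entry (90 days post-discharge) and closed at one year; and
`ascertain_death_or_readmission()` uses the same `(t₀, t₀ + horizon]`
convention, so an event on day 91 is outside a 90-day window.

# Validation metrics

`validate_model()` reports:

* **C statistic** via midranks (identical to exhaustive pair counting, ties
  = ½). The published validation does not state how its confidence
  intervals were produced, so the package default is a seeded nonparametric
  bootstrap (2,000 resamples, percentile interval), exposed as an explicit
  option rather than a silent analytic formula.
* **Brier score**, mean squared error of the risks.
* **Predicted-to-observed ratio**, mean predicted risk over prevalence.
* **Calibration intercept and slope.** The literature describes
  calibration-in-the-large verbally as a difference of mean risks, but
  reports values (e.g. an intercept of −0.93 next to a P:O of 2.04) that
  only make sense on the log-odds scale. The log-odds definition — the
  intercept of outcome ~ offset(PI), i.e. slope fixed at 1 — is therefore
  primary here, and the probability-scale difference is available separately
  as `calibration_mean_difference()`. Risks are clipped to
  `[1e-12, 1 − 1e-12]` before the logit transform.
* **Decile calibration table**: subjects ranked by risk with stable
  ordering, ten equal-count groups by rank, remainder subjects allocated to
  the lowest groups; this keeps groups well-defined under heavy ties (all
  risks equal collapses information but still partitions the cohort) and
  guarantees sizes sum to n. `autoplot()` draws the observed-vs-mean-
  predicted plot with a dashed identity line.

# Model updating

`recalibrate()` fits outcome ~ a + b·PI and returns the model with every
coefficient multiplied by b and intercept a + b·β₀; by construction its
predictions on the fitting cohort are calibrated (a = 0, b = 1) and its
discrimination is exactly the original's. `refit()` re-estimates the same
term structure de novo — same codings, same polynomial terms, no added
variables, so performance gains cannot come from model enrichment. Both use
binomial `glm` — iteratively reweighted least squares — with a tightened
convergence tolerance (relative deviance change < 1e-10, at most 100
iterations; in practice stricter than a 1e-8 coefficient-change rule) and
error with iteration diagnostics on non-convergence or signs of separation
(|coefficient| > 40), recommending a penalized fit rather than returning a
divergent one. No shrinkage is applied, matching the published analysis;
for small cohorts this is a documented limitation, not a feature. Updated
specs carry provenance (method, n, cohort hash, diagnostics, and the fitted
(a, b) for recalibration).

# Decision curve analysis

Net benefit at threshold probability p_t is
`TP/n − (FP/n) · p_t/(1 − p_t)`; `exchange_rate(p_t) = (1 − p_t)/p_t` makes
the implied tradeoff explicit (9 false positives per true positive at 0.1).
Strategies are first-class objects: model-guided (treat when risk ≥ p_t,
boundary inclusive, re-thresholded at every grid point), treat-all,
treat-none, and covariate rules (any AKI; AKI stage 2–3; discharge
eGFR < 30 as a pragmatic proxy for non-recovery). The default grid is 0.01
to 0.50 in steps of 0.01, covering the prespecified clinical thresholds
(1% and 10% for CKD progression, 30% for readmission); the published curves
state no axis range, so the grid is a documented choice. Curves are not
smoothed. `classification_table()` exposes the 2×2 counts behind any point,
and the identity between the counts and the net-benefit formula is enforced
by construction and re-checked in the test suite.

# Process mining

Event logs hold one row per care event (`case_id`, `activity`, `day` since
discharge) over a fixed activity vocabulary; `validate_event_log()` enforces
one discharge per case, time order, and a single terminal event last.
`truncate_to_horizon()` produces the 30- and 90-day views, closing
still-open cases with `end_follow_up` at the horizon boundary.
`directly_follows()` counts consecutive activity pairs within cases and
annotates each edge with the median transition time (midpoint convention
for even counts); flow conservation at non-terminal nodes and
terminal-arrival accounting are structural invariants. Conventions:
same-day ties are ordered by a declared priority (discharge, then
monitoring contacts, then terminal events); whether an A&E attendance
counts as "monitoring" is genuinely ambiguous in narrative descriptions of
unmonitored readmissions, so any recorded contact breaks "unmonitored"
status by default and `include_ae = FALSE` excludes A&E. Frequency-filtered
views (`top_k`) are provided for drawing "most common pathway" maps, with
no claimed fidelity to any particular commercial tool's filtering
heuristics.

# Synthetic data: what it emulates and what it does not

The generator exists so every stage of the pipeline is testable end to end.
`grampian_cohort_config()` and `alberta_cohort_config()` encode the
marginal covariate distributions and outcome prevalences of the two
validation settings (e.g. age 60.9 ± 19.8 and AKI stage mix 8.7/2.3/1.5%
for the all-survivor cohort at 2,927/26,575 prevalence; age 67.2 ± 15.4,
stage mix 78.5/13.2/8.3% and 140/9,382 prevalence for the AKI-survivor
cohort). Covariates are drawn **independently** — only marginals are
public, so no joint structure is claimed. Outcomes are drawn from
`plogis(shift + slope_factor · PI)` under a configured generating model,
with the shift solved (given the drawn covariates) so expected prevalence
hits its target, and `simulate_external_shift()` re-draws outcomes under a
drifted law — directly, or by bisecting the shift to hit a target
predicted-to-observed ratio.

The generating model for the all-survivor scenario deserves explanation.
The CKD model's printed coefficients produce realistic absolute risks, so
that scenario simply uses `alberta_original` as its truth. The readmissions
model's as-printed per-year age odds ratio saturates predicted risks at
adult ages, which would make simulated outcomes nearly deterministic in
age; a generating mechanism needs plausible risks. The packaged
`synthetic_grampian_truth` model (labelled synthetic in its file and notes)
therefore keeps the readmissions term structure but uses a plausible age
gradient (OR 1.017 per year) and the *refitted*-column AKI odds ratios
(3.43/5.63/5.04) — with these, simulated post-AKI event rates land around
29% of AKI discharges, matching the rates reported for the validation
setting, and overall prevalence is solved to ~0.11. This is a package
design choice for simulation, not a claim about the true derivation
coefficients.

Serial-creatinine series are generated by recipes constructed so that
exactly the intended criterion fires at exactly the intended stage (one
structural consequence: an absolute 48-hour delta can only be the
highest-stage criterion at stage 1, because any doubling also trips the
ratio rules, so stages 2–3 are allocated to ratio criteria). Care pathways
give poor-outcome cases a terminal event at a truncated-exponential time
(median 13 days by default, matching the reported median time to
unmonitored outcomes) preceded by monitoring contacts with probability
`monitoring_prob` — the default 0.61 reproduces the reported 39%
unmonitored fraction — and other cases a Poisson number of contacts before
`end_follow_up`.

What passing tests on these data do **not** show: performance on real
cohorts. The generator has no covariate correlations (real AKI severity
correlates with age, kidney function and comorbidity), no informative
missingness beyond the unmeasured-albuminuria category, no record-linkage
noise, and outcome laws that are exactly logistic in the generating PI.
Analytic identities (refit calibration, oracle equivalences, flow
conservation) transfer to real data; empirical magnitudes do not.

# Numerical choices and problem sizes

All random draws go through explicit seeds; generators save and restore the
caller's RNG state. Risks are clipped before logit transforms; `uniroot`
solves intercept shifts on `[-50, 50]` to tolerance 1e-10; GLM fits use
deviance tolerance 1e-10 with a 100-iteration cap. The test and acceptance
runs use cohort sizes chosen to make their checks sharp but quick: 25,000
subjects for the refit identities (tolerance 1e-3 against solver error),
50,000 for recovering a generated (−0.7, 0.8) calibration drift within
±0.05, 2,000 vs 20,000 for the 1/√n coefficient-error scaling, 20,000 for
the decision-curve ordering on a two-fold overpredicted cohort, 10,000
cases for the unmonitored-rate recovery, and 100 random cohorts of up to
200 subjects for exhaustive-pair oracle equivalence.

# Known limitations

* The as-printed readmissions models are faithful to publication but their
  absolute risks are not clinically interpretable (age coding); use the
  refitted spec or update on your own cohort before reading risks off them.
* No penalized fitting: separation in small or sparse cohorts errors out
  rather than being absorbed.
* Confidence intervals are provided for the C statistic only; interval
  methodology for the other metrics is deliberately out of scope.
* Decision curves carry no uncertainty bands by default; the bootstrap
  machinery exists but the published analysis shows none.
* The event-log vocabulary is fixed to the seven post-discharge activities;
  richer logs must be mapped onto it.
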