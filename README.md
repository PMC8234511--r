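# postaki

Validation, updating, and decision analysis of risk prediction models for
outcomes after acute kidney injury (AKI).

About one in seven hospital inpatients develops AKI, and survivors face high
risks of early death or unplanned readmission and of progression to advanced
chronic kidney disease (CKD G4–G5, eGFR < 30 mL/min/1.73 m²). Two published
logistic models address who to follow up after discharge: a 90-day
death-or-readmission model for all hospital survivors (with AKI stage as a key
predictor) and a 1-year CKD G4–G5 progression model for AKI survivors. For a
model to be worth acting on it must discriminate, be calibrated in the target
population, and — decisively — yield decisions that do more good than harm
compared with simpler strategies such as "follow up everyone with AKI". This
package provides the full pipeline for that assessment, aimed at
biostatisticians and clinical-epidemiology researchers working on post-AKI
care: external validation, model updating, decision curve analysis, KDIGO
AKI staging from serial creatinine, care-pathway process mining, and a
synthetic-cohort generator so the whole pipeline runs without patient data.

## Methods at its core

**Scoring.** A model is data: an intercept β₀ and coded terms with
coefficients β (stored as the natural logs of the published odds ratios).
The prognostic index of subject *i* is PI_i = β₀ + Σ_j β_j x_ij and the
predicted risk is p_i = expit(PI_i).

**Validation.** Discrimination by the C statistic (probability that an event
case is ranked above a non-event case; ties count ½), accuracy by the Brier
score, and calibration by the predicted-to-observed ratio, the calibration
intercept *a* (from the logistic fit of the outcome on PI with slope fixed
at 1) and calibration slope *b* (from outcome ~ a + b·PI), plus the decile
calibration table behind the usual calibration plot. Perfect calibration:
a = 0, b = 1; overprediction: a < 0.

**Updating.** Logistic recalibration rescales the model by the fitted
(a, b): β → b·β, β₀ → a + b·β₀, which restores calibration on the new
population while leaving discrimination untouched; refitting re-estimates
exactly the original term structure by maximum likelihood, so that on the
fitting cohort a = 0, b = 1 and P:O = 1 identically.

**Decision analysis.** For a strategy that selects TP true positives and FP
false positives out of n subjects at threshold probability p_t,

    NB(p_t) = TP/n − (FP/n) · p_t/(1 − p_t)

A threshold of 0.1 values one found case at 9 avoided unnecessary
follow-ups (`exchange_rate(0.1)` = 9). Decision curves compare model-guided
follow-up with treat-all, treat-none, any-AKI, severe-AKI (stage 2–3) and
discharge-eGFR < 30 rules across a threshold grid.

**Process mining.** Post-discharge event logs (discharge, GP monitoring,
outpatient clinic, A&E, readmission, death, end of follow-up) become
directly-follows graphs with case counts and median transition times, and
the package quantifies *unmonitored poor outcomes*: readmissions or deaths
with no intervening care contact.

## Worked example

Validate the as-printed CKD G4–G5 progression model on a synthetic cohort
shaped like its external validation setting (n = 9,382, ~1.5% prevalence),
recalibrate it, and compare follow-up strategies at the prespecified 1% and
10% thresholds:

```r
library(postaki)

cohort <- simulate_cohort(alberta_cohort_config(n = 9382), seed = 2026)
model  <- load_model("alberta_original")

validate_model(cohort, model)
#> <validation_report> model alberta_original on n = 9382 (129 events)
#>   C statistic            0.852
#>   Brier score            0.0137
#>   Predicted:observed     1.901
#>   Calibration intercept  -0.706
#>   Calibration slope      0.985

validate_model(cohort, recalibrate(model, cohort))
#> <validation_report> model alberta_original_recalibrated on n = 9382 (129 events)
#>   C statistic            0.852
#>   Brier score            0.0130
#>   Predicted:observed     1.000
#>   Calibration intercept  0.000
#>   Calibration slope      1.000
```

The model discriminates well (C = 0.852) but overpredicts roughly two-fold
(P:O = 1.90, negative calibration intercept) on this deliberately drifted
cohort; recalibration restores a = 0, b = 1 exactly while the C statistic is
unchanged. Decision analysis then asks whether acting on the model beats
simpler rules:

```r
decision_curve(
  cohort,
  list(model_strategy(model, "CKD risk model"),
       strategy_aki_stage_2_3(), strategy_discharge_egfr_lt_30(),
       treat_all(), treat_none()),
  ckd_g45_1y, thresholds = c(0.01, 0.10)
)
#>               strategy threshold  tp   fp percent_correct net_benefit
#> 1       CKD risk model      0.01 122 4583           51.08    0.008069
#> 2       CKD risk model      0.10  51  478           94.07   -0.000225
#> 3     AKI stage 2 or 3      0.01  38 2023           77.47    0.001872
#> ...
```

At the 1% threshold the model-guided strategy has the highest net benefit
(0.0081 ≈ 8 net true positives per 1,000 subjects after penalizing false
positives at 1:99 odds), ahead of severe-AKI (0.0019), discharge-eGFR < 30
(0.0001), treat-all (0.0038) and treat-none (0); `autoplot()` on the
returned object draws the corresponding decision curves, and
`classification_table()` the 2×2 behind any point.

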