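{
  "name": "aberdeen_original",
  "label": "Aberdeen readmissions model (derivation, Grampian 2003)",
  "outcome": "death_or_readmission_90d",
  "intercept": -1.876,
  "notes": [
    "Coefficients are natural logs of the published odds ratios at printed precision.",
    "The per-year age odds ratio is implausibly large for a 1-year unit but is kept exactly as published; absolute risks saturate at adult ages.",
    "Baseline eGFR is modelled per 10 mL/min/1.73m2 with linear plus quadratic terms; predictors are not centered."
  ],
  "terms": [
    {"predictor": "age", "type": "continuous", "scale": 1, "degree": 1, "odds_ratio": 1.17},
    {"predictor": "residential_care", "type": "binary", "odds_ratio": 1.37},
    {"predictor": "rural", "type": "binary", "odds_ratio": 0.86},
    {"predictor": "prior_admissions", "type": "count", "odds_ratio": 1.23},
    {"predictor": "emergency_admission", "type": "binary", "odds_ratio": 1.89},
    {"predictor": "aki_stage", "type": "categorical", "levels": ["0", "1", "2", "3"], "reference": "0", "level": "1", "odds_ratio": 1.50},
    {"predictor": "aki_stage", "type": "categorical", "levels": ["0", "1", "2", "3"], "reference": "0", "level": "2", "odds_ratio": 2.23},
    {"predictor": "aki_stage", "type": "categorical", "levels": ["0", "1", "2", "3"], "reference": "0", "level": "3", "odds_ratio": 2.80},
    {"predictor": "baseline_egfr", "type": "continuous", "scale": 10, "degree": 1, "odds_ratio": 0.87},
    {"predictor": "baseline_egfr", "type": "continuous", "scale": 10, "degree": 2, "odds_ratio": 1.01},
    {"predictor": "cancer", "type": "binary", "odds_ratio": 1.59},
    {"predictor": "cardiac_failure", "type": "binary", "odds_ratio": 1.42},
    {"predictor": "diabetes", "type": "binary", "odds_ratio": 1.38},
    {"predictor": "pulmonary", "type": "binary", "odds_ratio": 1.47}
  ]
}
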