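{
  "name": "aberdeen_refit",
  "label": "Aberdeen readmissions model (refitted, Grampian 2012 validation cohort)",
  "outcome": "death_or_readmission_90d",
  "intercept": -2.196,
  "notes": [
    "Published refitted column: same term structure as the original, re-estimated on the external validation cohort.",
    "Coefficients are natural logs of the published odds ratios at printed precision."
  ],
  "terms": [
    {"predictor": "age", "type": "continuous", "scale": 1, "degree": 1, "odds_ratio": 1.29},
    {"predictor": "residential_care", "type": "binary", "odds_ratio": 2.46},
    {"predictor": "rural", "type": "binary", "odds_ratio": 0.95},
    {"predictor": "prior_admissions", "type": "count", "odds_ratio": 1.26},
    {"predictor": "emergency_admission", "type": "binary", "odds_ratio": 2.2},
    {"predictor": "aki_stage", "type": "categorical", "levels": ["0", "1", "2", "3"], "reference": "0", "level": "1", "odds_ratio": 3.43},
    {"predictor": "aki_stage", "type": "categorical", "levels": ["0", "1", "2", "3"], "reference": "0", "level": "2", "odds_ratio": 5.63},
    {"predictor": "aki_stage", "type": "categorical", "levels": ["0", "1", "2", "3"], "reference": "0", "level": "3", "odds_ratio": 5.04},
    {"predictor": "baseline_egfr", "type": "continuous", "scale": 10, "degree": 1, "odds_ratio": 0.65},
    {"predictor": "baseline_egfr", "type": "continuous", "scale": 10, "degree": 2, "odds_ratio": 1.03},
    {"predictor": "cancer", "type": "binary", "odds_ratio": 1.9},
    {"predictor": "cardiac_failure", "type": "binary", "odds_ratio": 1.18},
    {"predictor": "diabetes", "type": "binary", "odds_ratio": 1.21},
    {"predictor": "pulmonary", "type": "binary", "odds_ratio": 1.46}
  ]
}
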