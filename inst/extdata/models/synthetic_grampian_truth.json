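{
  "name": "synthetic_grampian_truth",
  "label": "SYNTHETIC generating model for Grampian-like simulated cohorts (not a published model)",
  "outcome": "death_or_readmission_90d",
  "intercept": -3.4,
  "notes": [
    "SYNTHETIC: this model is a package-constructed data-generating mechanism for simulation, not a published fit.",
    "It keeps the Aberdeen readmissions term structure but replaces the implausible as-printed per-year age odds ratio (1.17) with a plausible gradient (1.017 per year), and uses the published refitted-column AKI stage odds ratios so that simulated event rates after AKI (~29% of AKI discharges) match the rates reported for the validation setting.",
    "The intercept is a baseline value; cohort simulation solves an additive shift so the simulated prevalence hits its configured target."
  ],
  "terms": [
    {"predictor": "age", "type": "continuous", "scale": 1, "degree": 1, "odds_ratio": 1.017},
    {"predictor": "residential_care", "type": "binary", "odds_ratio": 1.37},
    {"predictor": "rural", "type": "binary", "odds_ratio": 0.86},
    {"predictor": "prior_admissions", "type": "count", "odds_ratio": 1.23},
    {"predictor": "emergency_admission", "type": "binary", "odds_ratio": 1.89},
    {"predictor": "aki_stage", "type": "categorical", "levels": ["0", "1", "2", "3"], "reference": "0", "level": "1", "odds_ratio": 3.43},
    {"predictor": "aki_stage", "type": "categorical", "levels": ["0", "1", "2", "3"], "reference": "0", "level": "2", "odds_ratio": 5.63},
    {"predictor": "aki_stage", "type": "categorical", "levels": ["0", "1", "2", "3"], "reference": "0", "level": "3", "odds_ratio": 5.04},
    {"predictor": "baseline_egfr", "type": "continuous", "scale": 10, "degree": 1, "odds_ratio": 0.87},
    {"predictor": "baseline_egfr", "type": "continuous", "scale": 10, "degree": 2, "odds_ratio": 1.01},
    {"predictor": "cancer", "type": "binary", "odds_ratio": 1.59},
    {"predictor": "cardiac_failure", "type": "binary", "odds_ratio": 1.42},
    {"predictor": "diabetes", "type": "binary", "odds_ratio": 1.38},
    {"predictor": "pulmonary", "type": "binary", "odds_ratio": 1.47}
  ]
}
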