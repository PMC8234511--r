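{
  "name": "alberta_original",
  "label": "Alberta CKD G4-G5 progression model (derivation, Alberta)",
  "outcome": "ckd_g45_1y",
  "intercept": -9.246,
  "notes": [
    "Coefficients are natural logs of the published odds ratios at printed precision.",
    "The discharge creatinine reference category printed as '<0.1 mg/dL' is treated as a typographical error for '<1.0 mg/dL', consistent with the cohort characteristic tables.",
    "Baseline serum creatinine is modelled per 0.1 mg/dL; 'unmeasured' albuminuria is a genuine category, not missing data."
  ],
  "terms": [
    {"predictor": "age", "type": "continuous", "scale": 1, "degree": 1, "odds_ratio": 1.02},
    {"predictor": "female", "type": "binary", "odds_ratio": 2.93},
    {"predictor": "aki_stage", "type": "categorical", "levels": ["1", "2", "3"], "reference": "1", "level": "2", "odds_ratio": 1.28},
    {"predictor": "aki_stage", "type": "categorical", "levels": ["1", "2", "3"], "reference": "1", "level": "3", "odds_ratio": 2.47},
    {"predictor": "baseline_scr", "type": "continuous", "scale": 0.1, "degree": 1, "odds_ratio": 1.18},
    {"predictor": "discharge_scr_cat", "type": "categorical", "levels": ["<1.0", "1.0-<1.3", "1.3-<1.6", "1.6-<1.9", ">1.9"], "reference": "<1.0", "level": "1.0-<1.3", "odds_ratio": 2.93},
    {"predictor": "discharge_scr_cat", "type": "categorical", "levels": ["<1.0", "1.0-<1.3", "1.3-<1.6", "1.6-<1.9", ">1.9"], "reference": "<1.0", "level": "1.3-<1.6", "odds_ratio": 7.78},
    {"predictor": "discharge_scr_cat", "type": "categorical", "levels": ["<1.0", "1.0-<1.3", "1.3-<1.6", "1.6-<1.9", ">1.9"], "reference": "<1.0", "level": "1.6-<1.9", "odds_ratio": 11.35},
    {"predictor": "discharge_scr_cat", "type": "categorical", "levels": ["<1.0", "1.0-<1.3", "1.3-<1.6", "1.6-<1.9", ">1.9"], "reference": "<1.0", "level": ">1.9", "odds_ratio": 37.01},
    {"predictor": "albuminuria", "type": "categorical", "levels": ["normal", "mild", "heavy", "unmeasured"], "reference": "normal", "level": "mild", "odds_ratio": 1.25},
    {"predictor": "albuminuria", "type": "categorical", "levels": ["normal", "mild", "heavy", "unmeasured"], "reference": "normal", "level": "heavy", "odds_ratio": 3.13},
    {"predictor": "albuminuria", "type": "categorical", "levels": ["normal", "mild", "heavy", "unmeasured"], "reference": "normal", "level": "unmeasured", "odds_ratio": 1.67}
  ]
}
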