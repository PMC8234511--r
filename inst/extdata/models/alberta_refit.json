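{
  "name": "alberta_refit",
  "label": "Alberta CKD G4-G5 progression model (refitted, Grampian 2011-2013 validation cohort)",
  "outcome": "ckd_g45_1y",
  "intercept": -8.755,
  "notes": [
    "Published refitted column: same term structure as the original, re-estimated on the external validation cohort.",
    "Coefficients are natural logs of the published odds ratios at printed precision."
  ],
  "terms": [
    {"predictor": "age", "type": "continuous", "scale": 1, "degree": 1, "odds_ratio": 1.02},
    {"predictor": "female", "type": "binary", "odds_ratio": 3.05},
    {"predictor": "aki_stage", "type": "categorical", "levels": ["1", "2", "3"], "reference": "1", "level": "2", "odds_ratio": 2.15},
    {"predictor": "aki_stage", "type": "categorical", "levels": ["1", "2", "3"], "reference": "1", "level": "3", "odds_ratio": 2.82},
    {"predictor": "baseline_scr", "type": "continuous", "scale": 0.1, "degree": 1, "odds_ratio": 1.21},
    {"predictor": "discharge_scr_cat", "type": "categorical", "levels": ["<1.0", "1.0-<1.3", "1.3-<1.6", "1.6-<1.9", ">1.9"], "reference": "<1.0", "level": "1.0-<1.3", "odds_ratio": 4.1},
    {"predictor": "discharge_scr_cat", "type": "categorical", "levels": ["<1.0", "1.0-<1.3", "1.3-<1.6", "1.6-<1.9", ">1.9"], "reference": "<1.0", "level": "1.3-<1.6", "odds_ratio": 7.92},
    {"predictor": "discharge_scr_cat", "type": "categorical", "levels": ["<1.0", "1.0-<1.3", "1.3-<1.6", "1.6-<1.9", ">1.9"], "reference": "<1.0", "level": "1.6-<1.9", "odds_ratio": 11.31},
    {"predictor": "discharge_scr_cat", "type": "categorical", "levels": ["<1.0", "1.0-<1.3", "1.3-<1.6", "1.6-<1.9", ">1.9"], "reference": "<1.0", "level": ">1.9", "odds_ratio": 21.74},
    {"predictor": "albuminuria", "type": "categorical", "levels": ["normal", "mild", "heavy", "unmeasured"], "reference": "normal", "level": "mild", "odds_ratio": 0.95},
    {"predictor": "albuminuria", "type": "categorical", "levels": ["normal", "mild", "heavy", "unmeasured"], "reference": "normal", "level": "heavy", "odds_ratio": 2.00},
    {"predictor": "albuminuria", "type": "categorical", "levels": ["normal", "mild", "heavy", "unmeasured"], "reference": "normal", "level": "unmeasured", "odds_ratio": 0.78}
  ]
}
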