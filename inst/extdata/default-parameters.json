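{
  "risk_table": [
    {
      "age_lo": 50,
      "age_hi": 55,
      "vertebra": 0.031,
      "hip": 0,
      "wrist": 0.0299
    },
    {
      "age_lo": 55,
      "age_hi": 60,
      "vertebra": 0.0359,
      "hip": 0.0006,
      "wrist": 0.032
    },
    {
      "age_lo": 60,
      "age_hi": 65,
      "vertebra": 0.0415,
      "hip": 0.002,
      "wrist": 0.0318
    },
    {
      "age_lo": 65,
      "age_hi": 70,
      "vertebra": 0.0481,
      "hip": 0.0034,
      "wrist": 0.0206
    },
    {
      "age_lo": 70,
      "age_hi": 75,
      "vertebra": 0.0556,
      "hip": 0.0065,
      "wrist": 0.0197
    },
    {
      "age_lo": 75,
      "age_hi": 80,
      "vertebra": 0.0644,
      "hip": 0.0104,
      "wrist": 0.0117
    },
    {
      "age_lo": 80,
      "age_hi": 85,
      "vertebra": 0.0745,
      "hip": 0.0162,
      "wrist": 0.0092
    },
    {
      "age_lo": 85,
      "age_hi": null,
      "vertebra": 0.0862,
      "hip": 0.0352,
      "wrist": 0.0092
    }
  ],
  "rr_prior": {
    "vertebra": 2,
    "hip": 2,
    "wrist": 1.9
  },
  "rr_state": [
    {
      "state": "post_vertebral",
      "vertebra": 4.4,
      "hip": 2.3,
      "wrist": 1.4,
      "_row": "post_vertebral"
    },
    {
      "state": "post_hip",
      "vertebra": 2.5,
      "hip": 2.3,
      "wrist": null,
      "_row": "post_hip"
    },
    {
      "state": "post_wrist",
      "vertebra": 1.7,
      "hip": 1.9,
      "wrist": 3.3,
      "_row": "post_wrist"
    }
  ],
  "treat_mult": [
    {
      "state": "pmo",
      "vertebra": 0.526,
      "hip": 0.672,
      "wrist": 0.833,
      "_row": "pmo"
    },
    {
      "state": "post_vertebral",
      "vertebra": 0.575,
      "hip": 0.62,
      "wrist": null,
      "_row": "post_vertebral"
    },
    {
      "state": "post_hip",
      "vertebra": null,
      "hip": 0.62,
      "wrist": null,
      "_row": "post_hip"
    },
    {
      "state": "post_wrist",
      "vertebra": 0.575,
      "hip": 0.62,
      "wrist": 0.566,
      "_row": "post_wrist"
    }
  ],
  "persistence": {
    "b": 0.196,
    "floor": 0.2,
    "floor_onset": 60,
    "min_duration": 1
  },
  "residual": {
    "a": 13.5,
    "k": 0.048
  },
  "costs": {
    "management": {
      "vertebra": 5872,
      "hip": 11419,
      "wrist": 3305
    },
    "drug_price_12wk": 52.23,
    "drug_price_12wk_branded": 87.46,
    "weeks_per_year": 52,
    "drug_cost_months_cap": 48,
    "discount_rate": 0.05,
    "symptomatic_fraction": 0.23,
    "national_population": 1130000,
    "horizon_years": 10
  },
  "na_policy": "nearest"
}
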