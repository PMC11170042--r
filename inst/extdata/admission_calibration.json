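{
  "description": "Cohort-mean calibration constants for the synthetic generator and the aggregation-contract checks: subacute stroke rehabilitation inpatients (n = 11), 48-h chest-strap recordings at admission (0W) and 4 weeks (4W).",
  "hrr_mean_pct": {
    "total_24h_0w": 11.05,
    "total_24h_4w": 10.88,
    "training_0w": 22.13,
    "training_4w": 21.54,
    "nontraining_0w": 9.47,
    "nontraining_4w": 9.36
  },
  "msda_daily": {
    "admission": { "total": 13.09, "training": 4.44, "nontraining": 8.65 },
    "week4": { "total": 17.08, "training": 7.67, "nontraining": 9.41 }
  }
}
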