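{
  "version": "1.0",
  "description": "Marginal counts transcribed from the published multicenter pediatric septic shock validation cohort (n=363). Sufficient to reconstruct every 2x2 table behind the published Day-3 severe AKI diagnostic metrics and relative risks.",
  "n_total": 363,
  "n_d3_aki": 79,
  "n_day1_krt": 26,
  "classifiers": {
    "srai": { "n_positive": 140, "n_true_positive": 67 },
    "rai": { "n_positive": 195, "n_true_positive": 76 },
    "d1scr": { "n_positive": 253, "n_true_positive": 71 }
  },
  "outcomes": {
    "krt_by_srai": { "events_positive": 45, "events_negative": 4 },
    "mortality_by_srai": { "events_positive": 16, "events_negative": 10 },
    "mortality_by_aki": { "events_aki": 15, "events_no_aki": 11 },
    "n_krt_total": 49,
    "n_mortality_total": 26
  }
}
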