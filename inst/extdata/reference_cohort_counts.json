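{
  "description": "Printed summary counts from the 108-patient EVT development cohort (acute MCAO, ABZA-graded, 90-day mRS outcome). Positive test = good collaterals (grade > 2); positive state = favorable outcome (mRS <= 2).",
  "cohort": {
    "n": 108,
    "favorable_mrs_le2": 37
  },
  "two_by_two": {
    "tp": 28,
    "fn": 9,
    "fp": 8,
    "tn": 63
  },
  "outcome_by_collateral": {
    "good_collateral": { "n": 36, "mrs_le2": 28 },
    "poor_collateral": { "n": 72, "mrs_le2": 9 }
  },
  "grade_gt2_by_toast": {
    "CE":  { "n": 59, "gt2": 10 },
    "LAA": { "n": 44, "gt2": 23 }
  },
  "grade_margins_by_outcome": {
    "comment": "columns: mRS > 2 (n=71), mRS <= 2 (n=37); rows: ABZA grade 0..4",
    "mrs_gt2": [4, 28, 31, 6, 2],
    "mrs_le2": [0, 2, 7, 25, 3]
  },
  "reported": {
    "sensitivity_pct": 75.7,
    "specificity_pct": 88.7,
    "youden": 0.644,
    "prevalence_pct": 34.3,
    "mrs_le2_good_collateral_pct": 78,
    "mrs_le2_poor_collateral_pct": 13,
    "grade_gt2_ce_pct": 17,
    "grade_gt2_laa_pct": 52,
    "grade2_to_3_boundary_deg": 57.5
  }
}
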