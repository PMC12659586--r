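{
  "trial_id": "CVOT-1",
  "followup_years": 3,
  "criteria": [
    {"kind": "age_range", "min": 50},
    {"kind": "diagnosis_required",
     "conditions": ["coronary artery disease", "stroke", "peripheral artery disease", "heart failure"],
     "label": "established cardiovascular disease"},
    {"kind": "egfr_range", "min": 30, "lookback_days": 730}
  ]
}
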