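{
  "trial_id": "GLYCO-1",
  "followup_years": 1,
  "criteria": [
    {"kind": "age_range", "min": 18, "max": 70},
    {"kind": "lab_range", "analyte": "hba1c", "min": 7, "max": 10,
     "lookback_days": 730},
    {"kind": "egfr_range", "min": 60, "lookback_days": 730},
    {"kind": "diagnosis_excluded",
     "conditions": ["heart failure", "chronic liver disease", "solid organ cancer", "haematological cancer"],
     "label": "no major organ disease"},
    {"kind": "procedure_excluded", "codes": ["pbar01", "pbar02"],
     "window_days": 730, "label": "no bariatric surgery within 2 years"}
  ]
}
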