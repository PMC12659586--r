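{
  "trial_id": "BROAD-1",
  "followup_years": 2,
  "criteria": [
    {"kind": "age_range", "min": 18, "max": 85}
  ]
}
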