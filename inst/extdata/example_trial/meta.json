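{
  "surgeon_id": "demo",
  "group": "experienced",
  "exercise_id": "Camera Targeting-Level 1",
  "sample_rate_hz": 5,
  "units": "m"
}
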