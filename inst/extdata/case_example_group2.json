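{
  "age": 67,
  "sex": "F",
  "dose_mg": 2500,
  "plasma_at_ng_ml": 640,
  "plasma_nt_ng_ml": 310,
  "ecg_window_h": [2, 6],
  "rr_ms": 480,
  "prior_treatment": true,
  "ions": {"K": 3.8}
}
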