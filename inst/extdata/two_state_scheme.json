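{
  "states": ["closed", "open"],
  "conducting": {"open": 1.0},
  "transitions": [
    {"from": "closed", "to": "open", "type": "exponential", "a": 0.8, "b": 0.02},
    {"from": "open", "to": "closed", "type": "exponential", "a": 0.5, "b": -0.03}
  ],
  "g_single": 5.0,
  "g_max": 4.0
}
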