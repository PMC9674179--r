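{
  "lambda": 3.092428,
  "k_tether": 1.0,
  "tether_pairs": 12,
  "umbrella": {
    "r_min": 4,
    "r_max": 30,
    "n_windows": 14,
    "k_bias": 2,
    "n_steps": 200000,
    "stride": 200,
    "temperature": 300
  },
  "umbrella_ddg": {
    "n_windows": 20,
    "k_bias": 4,
    "n_steps": 400000
  },
  "target_affinity": 8,
  "target_ddg": 2,
  "lambda_bracket": [
    2.4,
    3.4
  ]
}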