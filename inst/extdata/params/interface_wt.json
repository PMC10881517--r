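{
  "label": "tip-link interface, wild type",
  "variant": "WT",
  "k_minus1_0": 0.5,
  "x_beta": 1.0,
  "k_plus1": 2.8,
  "k_plus2": 30.2,
  "F_C1": 58.0,
  "F_C2": 100.0,
  "n": 2.3,
  "kBT": 41.14
}
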