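{
  "label": "tip-link interface, R113G mutant",
  "variant": "mutant",
  "k_minus1_0": 0.3,
  "x_beta": 0.6,
  "k_plus1": 0.6,
  "k_plus2": 0.0,
  "F_C1": 58.0,
  "F_C2": 100.0,
  "n": 1.0,
  "kBT": 41.14
}
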