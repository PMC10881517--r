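{
  "label": "Cdh23 EC1-27 / Pcdh15 EC1-2 individual tip-link",
  "variant": "WT",
  "k_minus1_0": 0.29,
  "x_beta": 0.6,
  "k_plus1": 0.5,
  "k_plus2": 0.5,
  "F_C1": 58.0,
  "F_C2": 86.8,
  "n": 3.0,
  "kBT": 41.14
}
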