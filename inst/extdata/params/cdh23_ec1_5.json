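{
  "label": "Cdh23 EC1-5 / Pcdh15 EC1-2 individual tip-link",
  "variant": "WT",
  "k_minus1_0": 0.61,
  "x_beta": 1.2,
  "k_plus1": 0.9,
  "k_plus2": 29.4,
  "F_C1": 58.0,
  "F_C2": 108.4,
  "n": 1.2,
  "kBT": 41.14
}
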