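{
  "label": "Cdh23 EC1-21 / Pcdh15 EC1-2 individual tip-link",
  "variant": "WT",
  "k_minus1_0": 0.35,
  "x_beta": 0.7,
  "k_plus1": 1.2,
  "k_plus2": 0.8,
  "F_C1": 58.0,
  "F_C2": 72.0,
  "n": 3.8,
  "kBT": 41.14
}
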