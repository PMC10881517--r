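{
  "label": "Bell unfolding kinetics per step-height class, Cdh23 EC1-27 complex",
  "classes": [
    {"step_height": 4.2,  "k_u0": 0.17, "x_beta_u": 2.3},
    {"step_height": 13.2, "k_u0": 0.45, "x_beta_u": 1.0},
    {"step_height": 22.4, "k_u0": 0.45, "x_beta_u": 1.8},
    {"step_height": 33.6, "k_u0": 0.36, "x_beta_u": 0.7}
  ],
  "units": {"step_height": "nm", "k_u0": "1/s", "x_beta_u": "A"}
}
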