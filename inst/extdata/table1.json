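{
  "alpha7_Ftex": 0.166,
  "gamma7": 0.118,
  "gamma6": 0.0142,
  "alpha9": 0.283,
  "gamma9": 0.00031,
  "K47": 0.11,
  "alpha1_Feex_x2": 0.00015,
  "alpha6_x3_eff": 0.0019,
  "alpha4_storage": 0.001,
  "gamma4": 0.000125,
  "x6_total": 8.43373493975904,
  "frozen_core": true
}
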