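{
  "amlodipine": {"cmax_ng_ml": 3.200, "auc_0_inf": 160.65},
  "valsartan": {"cmax_ng_ml": 747.30, "auc_0_inf": 8949.70}
}
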