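{
  "kind": "fm_logistic",
  "schema_version": 1,
  "beta0": -3.354,
  "beta_iv": -0.010,
  "beta_apen": 0.895,
  "threshold": 0.15,
  "se": {
    "iv": 0.005,
    "apen": 0.294,
    "intercept": 1.336
  }
}
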