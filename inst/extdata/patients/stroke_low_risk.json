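{
  "sex": 1,
  "age": 60,
  "sbp": 120,
  "diabetes": 0,
  "prior_stroke": 0
}
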