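{
  "sex": 2,
  "age": 80,
  "sbp": 183,
  "diabetes": 1,
  "prior_stroke": 1
}
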