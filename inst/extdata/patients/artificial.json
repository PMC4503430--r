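{
  "gender": 1,
  "age": 62,
  "smoker": 1,
  "biomarker": 82
}
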