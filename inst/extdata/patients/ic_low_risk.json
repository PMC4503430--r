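{
  "sex": "male",
  "age": 55,
  "cholesterol": 190,
  "blood_pressure": "high normal",
  "cigarettes": 6,
  "diabetes": "yes",
  "chd": "no"
}
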