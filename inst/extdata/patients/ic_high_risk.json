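{
  "sex": "male",
  "age": 80,
  "cholesterol": 289,
  "blood_pressure": "stage 1",
  "cigarettes": 30,
  "diabetes": "yes",
  "chd": "yes"
}
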