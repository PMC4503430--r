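{
  "predictors": [
    {
      "name": "gender",
      "kind": "binary",
      "domain": ["0", "1"],
      "unit": ""
    },
    {
      "name": "age",
      "kind": "continuous",
      "domain": [30, 90],
      "unit": "years"
    },
    {
      "name": "smoker",
      "kind": "binary",
      "domain": ["0", "1"],
      "unit": ""
    },
    {
      "name": "biomarker",
      "kind": "continuous",
      "domain": [0, 200],
      "unit": "U/mL"
    }
  ],
  "intercept": -1,
  "terms": [
    {
      "id": "gender",
      "predictors": [
        "gender"
      ],
      "coefficient": -2,
      "transformation": {
        "form": "identity"
      }
    },
    {
      "id": "age",
      "predictors": [
        "age"
      ],
      "coefficient": 0.005,
      "transformation": {
        "form": "shifted_power",
        "c": 60,
        "k": 2
      }
    },
    {
      "id": "smoker",
      "predictors": [
        "smoker"
      ],
      "coefficient": 3,
      "transformation": {
        "form": "identity"
      }
    },
    {
      "id": "biomarker",
      "predictors": [
        "biomarker"
      ],
      "coefficient": -0.02,
      "transformation": {
        "form": "identity"
      }
    },
    {
      "id": "gender:age",
      "predictors": [
        "gender",
        "age"
      ],
      "coefficient": 0.3,
      "transformation": {
        "form": "product_of_two",
        "components": [
          {
            "form": "identity"
          },
          {
            "form": "scaled_power",
            "c": 60,
            "s": 10,
            "k": 3
          }
        ]
      }
    },
    {
      "id": "gender:smoker",
      "predictors": [
        "gender",
        "smoker"
      ],
      "coefficient": -2.5,
      "transformation": {
        "form": "product_of_two",
        "components": [
          {
            "form": "identity"
          },
          {
            "form": "identity"
          }
        ]
      }
    },
    {
      "id": "age:biomarker",
      "predictors": [
        "age",
        "biomarker"
      ],
      "coefficient": 5e-05,
      "transformation": {
        "form": "product_of_two",
        "components": [
          {
            "form": "shifted_power",
            "c": 60,
            "k": 2
          },
          {
            "form": "identity"
          }
        ]
      }
    }
  ],
  "link": {
    "family": "logistic"
  }
}
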