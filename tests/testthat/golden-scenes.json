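{
  "model_chart": {
    "kind": "model_chart",
    "bars": [
      {
        "id": "gender",
        "segments": 2
      },
      {
        "id": "age",
        "segments": 256
      },
      {
        "id": "smoker",
        "segments": 2
      },
      {
        "id": "biomarker",
        "segments": 256
      }
    ],
    "panels": [
      {
        "id": "gender:age",
        "dim": [
          2,
          101
        ]
      },
      {
        "id": "gender:smoker",
        "dim": [
          2,
          2
        ]
      },
      {
        "id": "age:biomarker",
        "dim": [
          101,
          101
        ]
      }
    ],
    "legend_steps": 64,
    "score_segments": 256,
    "marker_targets": [
      "bar",
      "bar",
      "bar",
      "bar",
      "panel",
      "panel",
      "panel",
      "score_bar"
    ],
    "percentile_lines": 4
  },
  "score_system_chart": {
    "kind": "score_system_chart",
    "bars": [
      {
        "id": "sex",
        "segments": 2,
        "labels": [
          "3",
          "0"
        ]
      },
      {
        "id": "age",
        "segments": 8,
        "labels": [
          "0",
          "1",
          "2",
          "3",
          "4",
          "5",
          "6",
          "7"
        ]
      },
      {
        "id": "cholesterol",
        "segments": 5,
        "labels": [
          "0",
          "1",
          "2",
          "3",
          "4"
        ]
      },
      {
        "id": "blood_pressure",
        "segments": 4,
        "labels": [
          "0",
          "1",
          "2",
          "4"
        ]
      },
      {
        "id": "cigarettes",
        "segments": 5,
        "labels": [
          "0",
          "1",
          "2",
          "3",
          "4"
        ]
      },
      {
        "id": "diabetes",
        "segments": 2,
        "labels": [
          "0",
          "5"
        ]
      },
      {
        "id": "chd",
        "segments": 2,
        "labels": [
          "0",
          "5"
        ]
      }
    ],
    "panels": [],
    "legend_steps": 64,
    "score_segments": 17,
    "marker_targets": [
      "bar",
      "bar",
      "bar",
      "bar",
      "bar",
      "bar",
      "bar",
      "score_bar"
    ],
    "percentile_lines": {}
  }
}
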