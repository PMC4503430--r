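{
  "predictors": [
    {
      "name": "sex",
      "bins": [
        {
          "match": {
            "type": "level",
            "level": "male"
          },
          "points": 3
        },
        {
          "match": {
            "type": "level",
            "level": "female"
          },
          "points": 0
        }
      ]
    },
    {
      "name": "age",
      "bins": [
        {
          "match": {
            "type": "range",
            "a": 45,
            "b": 49
          },
          "points": 0
        },
        {
          "match": {
            "type": "range",
            "a": 50,
            "b": 54
          },
          "points": 1
        },
        {
          "match": {
            "type": "range",
            "a": 55,
            "b": 59
          },
          "points": 2
        },
        {
          "match": {
            "type": "range",
            "a": 60,
            "b": 64
          },
          "points": 3
        },
        {
          "match": {
            "type": "range",
            "a": 65,
            "b": 69
          },
          "points": 4
        },
        {
          "match": {
            "type": "range",
            "a": 70,
            "b": 74
          },
          "points": 5
        },
        {
          "match": {
            "type": "range",
            "a": 75,
            "b": 79
          },
          "points": 6
        },
        {
          "match": {
            "type": "range",
            "a": 80,
            "b": 84
          },
          "points": 7
        }
      ]
    },
    {
      "name": "cholesterol",
      "bins": [
        {
          "match": {
            "type": "below",
            "a": 170
          },
          "points": 0
        },
        {
          "match": {
            "type": "range",
            "a": 170,
            "b": 209
          },
          "points": 1
        },
        {
          "match": {
            "type": "range",
            "a": 210,
            "b": 249
          },
          "points": 2
        },
        {
          "match": {
            "type": "range",
            "a": 250,
            "b": 289
          },
          "points": 3
        },
        {
          "match": {
            "type": "above",
            "b": 289
          },
          "points": 4
        }
      ]
    },
    {
      "name": "blood_pressure",
      "bins": [
        {
          "match": {
            "type": "level",
            "level": "normal"
          },
          "points": 0
        },
        {
          "match": {
            "type": "level",
            "level": "high normal"
          },
          "points": 1
        },
        {
          "match": {
            "type": "level",
            "level": "stage 1"
          },
          "points": 2
        },
        {
          "match": {
            "type": "level",
            "level": "stage 2+"
          },
          "points": 4
        }
      ]
    },
    {
      "name": "cigarettes",
      "bins": [
        {
          "match": {
            "type": "value",
            "value": 0
          },
          "points": 0
        },
        {
          "match": {
            "type": "range",
            "a": 1,
            "b": 5
          },
          "points": 1
        },
        {
          "match": {
            "type": "range",
            "a": 6,
            "b": 10
          },
          "points": 2
        },
        {
          "match": {
            "type": "range",
            "a": 11,
            "b": 20
          },
          "points": 3
        },
        {
          "match": {
            "type": "above",
            "b": 20
          },
          "points": 4
        }
      ]
    },
    {
      "name": "diabetes",
      "bins": [
        {
          "match": {
            "type": "level",
            "level": "no"
          },
          "points": 0
        },
        {
          "match": {
            "type": "level",
            "level": "yes"
          },
          "points": 5
        }
      ]
    },
    {
      "name": "chd",
      "bins": [
        {
          "match": {
            "type": "level",
            "level": "no"
          },
          "points": 0
        },
        {
          "match": {
            "type": "level",
            "level": "yes"
          },
          "points": 5
        }
      ]
    }
  ],
  "conversion": [
    {
      "scores": {
        "type": "below",
        "a": 10
      },
      "label": "< 1%"
    },
    {
      "scores": {
        "type": "range",
        "a": 10,
        "b": 12
      },
      "label": "1%"
    },
    {
      "scores": {
        "type": "range",
        "a": 13,
        "b": 15
      },
      "label": "2%"
    },
    {
      "scores": {
        "type": "range",
        "a": 16,
        "b": 17
      },
      "label": "3%"
    },
    {
      "scores": {
        "type": "value",
        "value": 18
      },
      "label": "4%"
    },
    {
      "scores": {
        "type": "value",
        "value": 19
      },
      "label": "5%"
    },
    {
      "scores": {
        "type": "value",
        "value": 20
      },
      "label": "6%"
    },
    {
      "scores": {
        "type": "value",
        "value": 21
      },
      "label": "7%"
    },
    {
      "scores": {
        "type": "value",
        "value": 22
      },
      "label": "8%"
    },
    {
      "scores": {
        "type": "value",
        "value": 23
      },
      "label": "10%"
    },
    {
      "scores": {
        "type": "value",
        "value": 24
      },
      "label": "11%"
    },
    {
      "scores": {
        "type": "value",
        "value": 25
      },
      "label": "13%"
    },
    {
      "scores": {
        "type": "value",
        "value": 26
      },
      "label": "16%"
    },
    {
      "scores": {
        "type": "value",
        "value": 27
      },
      "label": "18%"
    },
    {
      "scores": {
        "type": "value",
        "value": 28
      },
      "label": "21%"
    },
    {
      "scores": {
        "type": "value",
        "value": 29
      },
      "label": "24%"
    },
    {
      "scores": {
        "type": "value",
        "value": 30
      },
      "label": "28%"
    }
  ]
}
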