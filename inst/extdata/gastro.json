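{
  "disease": "gastrointestinal",
  "alpha": 0.25,
  "variables": [
    {
      "id": "leaving_home.duration", "label": "leaving_home", "aspect": "duration",
      "normal_min": 9000, "normal_max": 14400,
      "corners": {
        "abnormal_minus": [null, null, 3200, 5200],
        "normal": [4100, 9100, 14400, 16400],
        "abnormal_plus": [14400, 16400, null, null]
      }
    },
    {
      "id": "going_to_toilet.duration", "label": "going_to_toilet", "aspect": "duration",
      "normal_min": 2200, "normal_max": 3600,
      "corners": {
        "abnormal_minus": [null, null, 1850, 2200],
        "normal": [1850, 2200, 3600, 3950],
        "abnormal_plus": [3600, 3950, null, null]
      }
    },
    {
      "id": "eating.duration", "label": "eating", "aspect": "duration",
      "normal_min": 2880, "normal_max": 4500,
      "corners": {
        "abnormal_minus": [null, null, 2475, 2880],
        "normal": [2475, 2880, 4500, 4905],
        "abnormal_plus": [4500, 4905, null, null]
      }
    },
    {
      "id": "sleeping.duration", "label": "sleeping", "aspect": "duration",
      "normal_min": 31200, "normal_max": 40800,
      "corners": {
        "abnormal_minus": [null, null, 27600, 30600],
        "normal": [28200, 31200, 40800, 43800],
        "abnormal_plus": [40800, 43800, null, null]
      }
    },
    {
      "id": "leaving_home.frequency", "label": "leaving_home", "aspect": "frequency",
      "normal_min": 1, "normal_max": 2,
      "corners": {
        "abnormal_minus": [null, null, 0.5, 1],
        "normal": [0.5, 1, 2, 2.5],
        "abnormal_plus": [2, 2.5, null, null]
      }
    },
    {
      "id": "going_to_toilet.frequency", "label": "going_to_toilet", "aspect": "frequency",
      "normal_min": 10, "normal_max": 12,
      "corners": {
        "abnormal_minus": [null, null, 9.5, 10],
        "normal": [9.5, 10, 12, 12.5],
        "abnormal_plus": [12, 12.5, null, null]
      }
    },
    {
      "id": "eating.frequency", "label": "eating", "aspect": "frequency",
      "normal_min": 3, "normal_max": 4,
      "corners": {
        "abnormal_minus": [null, null, 2.5, 3],
        "normal": [2.5, 3, 4, 4.5],
        "abnormal_plus": [4, 4.5, null, null]
      }
    },
    {
      "id": "sleeping.frequency", "label": "sleeping", "aspect": "frequency",
      "normal_min": 1, "normal_max": 2,
      "corners": {
        "abnormal_minus": [null, null, 0.5, 1],
        "normal": [0.5, 1, 2, 2.5],
        "abnormal_plus": [2, 2.5, null, null]
      }
    }
  ],
  "rules": [
    {
      "consequent": "Low",
      "groups": [
        [{"variable": "eating.duration", "subset": "Normal"}],
        [{"variable": "eating.frequency", "subset": "Normal"}],
        [{"variable": "sleeping.duration", "subset": "Normal"}],
        [{"variable": "sleeping.frequency", "subset": "Normal"}],
        [{"variable": "leaving_home.duration", "subset": "Normal"}],
        [{"variable": "leaving_home.frequency", "subset": "Normal"}],
        [{"variable": "going_to_toilet.duration", "subset": "Normal"}],
        [{"variable": "going_to_toilet.frequency", "subset": "Normal"}]
      ]
    },
    {
      "consequent": "High",
      "groups": [
        [{"variable": "eating.frequency", "subset": "Abnormal-"}],
        [{"variable": "leaving_home.frequency", "subset": "Abnormal-"}],
        [{"variable": "sleeping.duration", "subset": "Abnormal-"}]
      ]
    },
    {
      "consequent": "Very high",
      "groups": [
        [{"variable": "eating.frequency", "subset": "Abnormal-"},
         {"variable": "eating.duration", "subset": "Abnormal-"}],
        [{"variable": "leaving_home.frequency", "subset": "Abnormal-"},
         {"variable": "leaving_home.duration", "subset": "Abnormal-"}],
        [{"variable": "going_to_toilet.duration", "subset": "Abnormal+"},
         {"variable": "going_to_toilet.frequency", "subset": "Abnormal+"}],
        [{"variable": "sleeping.duration", "subset": "Abnormal-"},
         {"variable": "sleeping.frequency", "subset": "Abnormal-"}]
      ]
    }
  ],
  "generate_complete": true,
  "count_thresholds": [2, 4],
  "output_sets": {
    "Low": [0, 0, 0.2, 0.4],
    "High": [0.2, 0.4, 0.6, 0.8],
    "Very high": [0.6, 0.8, 1, 1]
  },
  "cutpoints": [0.33333333, 0.66666667],
  "alerts": {
    "Low": "Minor",
    "High": "Important",
    "Very high": "Major"
  },
  "grid_n": 1001
}
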