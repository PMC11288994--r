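{
  "schema_version": "1.0",
  "note": "Prehospital-adapted screening instruments. Interval components list lower bounds of half-open bins over the plausibility range after quantization (integers; temperature to one decimal). SIRS omits leukocyte count and paCO2; MEWS omits urine output; NEWS2 uses SpO2 scale 1 only.",
  "tools": {
    "qsofa": {
      "label": "qSOFA",
      "threshold": 2,
      "max_score": 3,
      "components": [
        {"vital": "rr", "type": "interval", "lower": [1, 22], "points": [0, 1]},
        {"vital": "sbp", "type": "interval", "lower": [40, 101], "points": [1, 0]},
        {"vital": "gcs", "type": "interval", "lower": [3, 15], "points": [1, 0],
         "fallback": "consciousness"}
      ],
      "omitted": []
    },
    "sirs": {
      "label": "SIRS (prehospital)",
      "threshold": 2,
      "max_score": 3,
      "components": [
        {"vital": "temp", "type": "interval", "lower": [25, 36, 38.1], "points": [1, 0, 1]},
        {"vital": "hr", "type": "interval", "lower": [10, 91], "points": [0, 1]},
        {"vital": "rr", "type": "interval", "lower": [1, 21], "points": [0, 1]}
      ],
      "omitted": ["leukocyte_count", "paco2"]
    },
    "mews": {
      "label": "MEWS (prehospital)",
      "threshold": 4,
      "max_score": 14,
      "components": [
        {"vital": "sbp", "type": "interval", "lower": [40, 71, 81, 101, 200], "points": [3, 2, 1, 0, 2]},
        {"vital": "hr", "type": "interval", "lower": [10, 41, 51, 101, 111, 130], "points": [2, 1, 0, 1, 2, 3]},
        {"vital": "rr", "type": "interval", "lower": [1, 9, 15, 21, 30], "points": [2, 0, 1, 2, 3]},
        {"vital": "temp", "type": "interval", "lower": [25, 35, 38.5], "points": [2, 0, 2]},
        {"vital": "consciousness", "type": "category",
         "points": {"A": 0, "C": 1, "V": 1, "P": 2, "U": 3}}
      ],
      "omitted": ["urine_output"]
    },
    "news2": {
      "label": "NEWS2",
      "threshold": 5,
      "max_score": 20,
      "components": [
        {"vital": "rr", "type": "interval", "lower": [1, 9, 12, 21, 25], "points": [3, 1, 0, 2, 3]},
        {"vital": "spo2", "type": "interval", "lower": [40, 92, 94, 96], "points": [3, 2, 1, 0]},
        {"vital": "on_oxygen", "type": "binary", "points": 2},
        {"vital": "sbp", "type": "interval", "lower": [40, 91, 101, 111, 220], "points": [3, 2, 1, 0, 3]},
        {"vital": "hr", "type": "interval", "lower": [10, 41, 51, 91, 111, 131], "points": [3, 1, 0, 1, 2, 3]},
        {"vital": "consciousness", "type": "category",
         "points": {"A": 0, "C": 3, "V": 3, "P": 3, "U": 3}},
        {"vital": "temp", "type": "interval", "lower": [25, 35.1, 36.1, 38.1, 39.1], "points": [3, 1, 0, 1, 2]}
      ],
      "omitted": []
    }
  }
}
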