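{
  "seed": 20160101,
  "strategies": ["hotdeck"],
  "precedence": "first",
  "cohort": {
    "n_cases": 4503,
    "sepsis_prevalence": 0.017321785,
    "mi_prevalence": 0.026,
    "stroke_prevalence": 0.027,
    "ep_fraction": 0.0315435,
    "implausible_rate": 0.01,
    "doc_correlation": 0.65,
    "doc_rates": {
      "temp":          {"PM": 0.177, "EP": 0.198},
      "rr":            {"PM": 0.270, "EP": 0.533},
      "gcs":           {"PM": 0.781, "EP": 0.678},
      "spo2":          {"PM": 0.790, "EP": 0.854},
      "sbp":           {"PM": 0.788, "EP": 0.869},
      "hr":            {"PM": 0.815, "EP": 0.887},
      "consciousness": {"PM": 0.869, "EP": 0.686}
    },
    "fatality": {
      "sepsis": {"hospital": 0.316, "d30": 0.317},
      "mi":     {"hospital": 0.125, "d30": 0.134},
      "stroke": {"hospital": 0.100, "d30": 0.118},
      "none":   {"hospital": 0.015, "d30": 0.020}
    },
    "suspicion_rates": {"PM": 0, "EP": 0.0014355}
  }
}
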