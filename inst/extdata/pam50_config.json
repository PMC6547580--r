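{
  "correlation_method": "spearman",
  "ambiguity_threshold": 0.10,
  "proliferation_genes": ["CCNB1", "UBE2C", "BIRC5", "KNTC2", "CDC20",
                          "PTTG1", "RRM2", "MKI67", "TYMS", "CEP55", "CDCA1"],
  "ror_coefficients": {
    "ror_s": {
      "weights": {"Basal": 0.05, "Her2": 0.12, "LumA": -0.34,
                  "LumB": 0.23, "Normal": 0},
      "proliferation_weight": 0,
      "bounds": [-0.74, 0.74]
    },
    "ror_ps": {
      "weights": {"Basal": 0.05, "Her2": 0.12, "LumA": -0.34,
                  "LumB": 0.23, "Normal": 0},
      "proliferation_weight": 0.17,
      "bounds": [-1.08, 1.08]
    }
  },
  "risk_cutoffs": {
    "ror_s": [29, 52],
    "ror_ps": [23, 52]
  },
  "tie_break": ["Basal", "Her2", "LumA", "LumB", "Normal"]
}
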