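{
  "name": "IPASS",
  "genes": ["NFATC3", "TNFRSF18", "NFKB1", "CD27", "CTLA4", "FPR2", "SERPING1", "CXCL9", "CXCL11", "LAMP3", "THBD", "SBNO2", "CD276", "LIF", "CXCL10"],
  "calibration": {
    "raw_min": 0.2,
    "raw_max": 1.88,
    "norm_threshold": -0.25,
    "raw_threshold": 0.83,
    "log_base": 2,
    "pseudocount": 1
  }
}
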