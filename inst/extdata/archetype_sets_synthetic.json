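{
  "scoring": "mean_zscore",
  "comment": "Synthetic example of the archetype gene-set input format. The twelve archetype names follow the immune-rich (IR) / immune-stromal-rich (ISR) / immune-desert (ID) naming style; the gene lists are small illustrative marker sets, NOT the published archetype signatures, which must be supplied by the user in this format.",
  "sets": {
    "IR CD8 Mac": ["CD8A", "CD8B", "GZMB", "PRF1", "CD68"],
    "IR CD8 Mono": ["CD8A", "GZMK", "CD14", "FCN1"],
    "IR CD4 Mac": ["CD4", "IL7R", "CD68", "MRC1"],
    "ISR CD8 Mac": ["CD8A", "COL1A1", "FAP", "CD68"],
    "ISR CD4 Mac": ["CD4", "COL1A2", "PDGFRB", "CD163"],
    "ID CD4 Mac": ["CD4", "CD68", "APOE"],
    "ID Mono": ["CD14", "FCN1", "S100A8"],
    "ID Mac": ["CD68", "CD163", "MARCO"],
    "ID cDC": ["CLEC9A", "XCR1", "BATF3"],
    "ID DC Mono": ["CD1C", "FCER1A", "CD14"],
    "Immune Rich cDC": ["CLEC9A", "LAMP3", "CCR7"],
    "Immune Stromal DC": ["COL1A1", "CD1C", "LUM"]
  }
}
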