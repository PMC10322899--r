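{
  "name": "oncotype_dx",
  "description": "Genomic Prostate Score research formula: 12 informative genes in four biological modules (stromal response, cellular organization, androgen signaling, proliferation), per-gene centering, module averages combined linearly with the published module weights.",
  "normalization": "center",
  "combination": "grouped_linear",
  "min_fraction": 0.5,
  "group_weights": {
    "stromal": 0.735,
    "cellular_organization": -0.368,
    "androgen": -0.352,
    "proliferation": 0.095
  },
  "components": [
    {"gene": "BGN", "aliases": [], "direction": 1, "weight": 1, "group": "stromal"},
    {"gene": "COL1A1", "aliases": [], "direction": 1, "weight": 1, "group": "stromal"},
    {"gene": "SFRP4", "aliases": [], "direction": 1, "weight": 1, "group": "stromal"},
    {"gene": "FLNC", "aliases": ["ABPL", "FLN2"], "direction": 1, "weight": 1, "group": "cellular_organization"},
    {"gene": "GSN", "aliases": [], "direction": 1, "weight": 1, "group": "cellular_organization"},
    {"gene": "TPM2", "aliases": [], "direction": 1, "weight": 1, "group": "cellular_organization"},
    {"gene": "GSTM2", "aliases": ["GST4"], "direction": 1, "weight": 1, "group": "cellular_organization"},
    {"gene": "FAM13C", "aliases": ["FAM13C1"], "direction": 1, "weight": 1, "group": "androgen"},
    {"gene": "KLK2", "aliases": [], "direction": 1, "weight": 1, "group": "androgen"},
    {"gene": "AZGP1", "aliases": ["ZAG"], "direction": 1, "weight": 1, "group": "androgen"},
    {"gene": "SRD5A2", "aliases": [], "direction": 1, "weight": 1, "group": "androgen"},
    {"gene": "TPX2", "aliases": ["C20orf1"], "direction": 1, "weight": 1, "group": "proliferation"}
  ]
}
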