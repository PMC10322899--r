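{
  "name": "prolaris",
  "description": "Cell-cycle progression (CCP) research score: 34 cell-cycle genes, per-gene centering of log2 expression, combined by the mean. Gene list transcribed from the published CCP signature with legacy symbols carried as aliases.",
  "normalization": "center",
  "combination": "mean",
  "min_fraction": 0.5,
  "components": [
    {"gene": "FOXM1", "aliases": ["MPP2"], "direction": 1, "weight": 1},
    {"gene": "CDC20", "aliases": ["p55CDC"], "direction": 1, "weight": 1},
    {"gene": "CDKN3", "aliases": ["KAP"], "direction": 1, "weight": 1},
    {"gene": "CDK1", "aliases": ["CDC2"], "direction": 1, "weight": 1},
    {"gene": "KIF11", "aliases": ["EG5", "KNSL1"], "direction": 1, "weight": 1},
    {"gene": "PCLAF", "aliases": ["KIAA0101", "PAF15"], "direction": 1, "weight": 1},
    {"gene": "NUSAP1", "aliases": [], "direction": 1, "weight": 1},
    {"gene": "CENPF", "aliases": [], "direction": 1, "weight": 1},
    {"gene": "ASPM", "aliases": ["MCPH5"], "direction": 1, "weight": 1},
    {"gene": "BUB1B", "aliases": ["BUBR1"], "direction": 1, "weight": 1},
    {"gene": "RRM2", "aliases": [], "direction": 1, "weight": 1},
    {"gene": "DLGAP5", "aliases": ["DLG7", "HURP"], "direction": 1, "weight": 1},
    {"gene": "BIRC5", "aliases": ["survivin"], "direction": 1, "weight": 1},
    {"gene": "KIF20A", "aliases": ["MKLP2"], "direction": 1, "weight": 1},
    {"gene": "PLK1", "aliases": [], "direction": 1, "weight": 1},
    {"gene": "PTTG1", "aliases": ["securin"], "direction": 1, "weight": 1},
    {"gene": "RAD54L", "aliases": [], "direction": 1, "weight": 1},
    {"gene": "PBK", "aliases": ["TOPK"], "direction": 1, "weight": 1},
    {"gene": "TK1", "aliases": [], "direction": 1, "weight": 1},
    {"gene": "CENPM", "aliases": ["PANE1"], "direction": 1, "weight": 1},
    {"gene": "PRC1", "aliases": [], "direction": 1, "weight": 1},
    {"gene": "CDCA8", "aliases": ["borealin"], "direction": 1, "weight": 1},
    {"gene": "MCM10", "aliases": [], "direction": 1, "weight": 1},
    {"gene": "ASF1B", "aliases": [], "direction": 1, "weight": 1},
    {"gene": "TOP2A", "aliases": [], "direction": 1, "weight": 1},
    {"gene": "CDCA3", "aliases": ["TOME1"], "direction": 1, "weight": 1},
    {"gene": "RAD51", "aliases": ["RECA"], "direction": 1, "weight": 1},
    {"gene": "CENPE", "aliases": [], "direction": 1, "weight": 1},
    {"gene": "SKA1", "aliases": ["C18orf24"], "direction": 1, "weight": 1},
    {"gene": "ORC6", "aliases": ["ORC6L"], "direction": 1, "weight": 1},
    {"gene": "KIF2C", "aliases": ["MCAK"], "direction": 1, "weight": 1},
    {"gene": "DTL", "aliases": ["CDT2", "RAMP"], "direction": 1, "weight": 1},
    {"gene": "PLK4", "aliases": ["SAK"], "direction": 1, "weight": 1},
    {"gene": "CDC45", "aliases": ["CDC45L"], "direction": 1, "weight": 1}
  ]
}
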