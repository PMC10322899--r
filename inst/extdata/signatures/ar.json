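{
  "name": "ar",
  "description": "Androgen receptor activity score: 20 AR-signaling target genes, per-gene z-score across samples, combined by the mean (sum-of-z-scores up to the 1/20 scale factor at full coverage).",
  "normalization": "zscore",
  "combination": "mean",
  "min_fraction": 0.5,
  "components": [
    {"gene": "KLK3", "aliases": ["PSA"], "direction": 1, "weight": 1},
    {"gene": "KLK2", "aliases": [], "direction": 1, "weight": 1},
    {"gene": "PMEPA1", "aliases": ["TMEPAI"], "direction": 1, "weight": 1},
    {"gene": "ABCC4", "aliases": ["MRP4"], "direction": 1, "weight": 1},
    {"gene": "NKX3-1", "aliases": ["NKX3.1", "NKX3A"], "direction": 1, "weight": 1},
    {"gene": "C1orf116", "aliases": ["SARG"], "direction": 1, "weight": 1},
    {"gene": "FKBP5", "aliases": [], "direction": 1, "weight": 1},
    {"gene": "ACSL3", "aliases": ["FACL3"], "direction": 1, "weight": 1},
    {"gene": "ZBTB10", "aliases": ["RINZF"], "direction": 1, "weight": 1},
    {"gene": "HERC3", "aliases": [], "direction": 1, "weight": 1},
    {"gene": "PTGER4", "aliases": ["EP4"], "direction": 1, "weight": 1},
    {"gene": "MPHOSPH9", "aliases": ["MPP9"], "direction": 1, "weight": 1},
    {"gene": "EAF2", "aliases": ["U19"], "direction": 1, "weight": 1},
    {"gene": "MED28", "aliases": ["EG1"], "direction": 1, "weight": 1},
    {"gene": "NNMT", "aliases": [], "direction": 1, "weight": 1},
    {"gene": "MAF", "aliases": ["c-MAF"], "direction": 1, "weight": 1},
    {"gene": "GNMT", "aliases": [], "direction": 1, "weight": 1},
    {"gene": "CENPN", "aliases": ["ICEN32"], "direction": 1, "weight": 1},
    {"gene": "ELL2", "aliases": [], "direction": 1, "weight": 1},
    {"gene": "TMPRSS2", "aliases": ["PRSS10"], "direction": 1, "weight": 1}
  ]
}
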