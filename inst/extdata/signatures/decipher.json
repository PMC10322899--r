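{
  "name": "decipher",
  "description": "Genomic-classifier research score: 20 RNA markers with signed directions, per-gene percentile rank across samples, combined as mean percentile of up-markers minus mean percentile of down-markers. Non-coding markers retain their feature names and are typically absent from gene-level matrices.",
  "normalization": "percentile",
  "combination": "signed_percentile_mean",
  "min_fraction": 0.5,
  "components": [
    {"gene": "LASP1", "aliases": ["MLN50"], "direction": 1, "weight": 1},
    {"gene": "IQGAP3", "aliases": [], "direction": 1, "weight": 1},
    {"gene": "NFIB", "aliases": [], "direction": 1, "weight": 1},
    {"gene": "THBS2", "aliases": ["TSP2"], "direction": 1, "weight": 1},
    {"gene": "UBE2C", "aliases": ["UBCH10"], "direction": 1, "weight": 1},
    {"gene": "NUSAP1", "aliases": [], "direction": 1, "weight": 1},
    {"gene": "ZWILCH", "aliases": [], "direction": 1, "weight": 1},
    {"gene": "CAMK2N1", "aliases": [], "direction": 1, "weight": 1},
    {"gene": "EPPK1", "aliases": [], "direction": 1, "weight": 1},
    {"gene": "PCDH7", "aliases": ["BHPCDH"], "direction": 1, "weight": 1},
    {"gene": "PCAT32", "aliases": [], "direction": 1, "weight": 1},
    {"gene": "LINC00161", "aliases": [], "direction": 1, "weight": 1},
    {"gene": "ANO7", "aliases": ["NGEP", "TMEM16G"], "direction": -1, "weight": 1},
    {"gene": "MYBPC1", "aliases": [], "direction": -1, "weight": 1},
    {"gene": "S1PR4", "aliases": ["EDG6"], "direction": -1, "weight": 1},
    {"gene": "RABGAP1", "aliases": ["TBC1D11"], "direction": -1, "weight": 1},
    {"gene": "PBX1", "aliases": [], "direction": -1, "weight": 1},
    {"gene": "TSBP1", "aliases": ["C6orf10"], "direction": -1, "weight": 1},
    {"gene": "TNFRSF19", "aliases": ["TROY"], "direction": -1, "weight": 1},
    {"gene": "GLYATL1P4", "aliases": ["PCAT80"], "direction": -1, "weight": 1}
  ]
}
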