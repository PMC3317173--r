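{
  "gene_a": "geneA",
  "gene_b": "geneB",
  "promoter_rho": -0.053769,
  "coding_rho": 0.517129,
  "promoter_n": 1000,
  "coding_n": 1300,
  "promoter_reason": "NA",
  "coding_reason": "NA",
  "resampled": false,
  "mode": "coverage",
  "length_policy": "resample_min"
}
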