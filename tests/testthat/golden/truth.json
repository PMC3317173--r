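{
  "config": {
    "seed": 42,
    "depth": 20
  },
  "paralog_pair": {
    "coding_shared": true,
    "promoter_shared": false
  },
  "gene_tree": {
    "n_species": 12,
    "n_duplications": 3,
    "planted_pairs": [
      {
        "species": "sp05",
        "gene_a": "g1",
        "gene_b": "g2"
      },
      {
        "species": "sp09",
        "gene_a": "g1",
        "gene_b": "g2"
      },
      {
        "species": "sp12",
        "gene_a": "g1",
        "gene_b": "g2"
      }
    ]
  }
}
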