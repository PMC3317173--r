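{
  "n_tips": 15,
  "n_species": 12,
  "n_multi_copy": 3,
  "n_duplications": 3,
  "duplication_nodes": [23, 27, 29],
  "sister_paralog_pairs": [
    {
      "species": "sp09",
      "gene_a": "g1",
      "gene_b": "g2"
    },
    {
      "species": "sp05",
      "gene_a": "g1",
      "gene_b": "g2"
    },
    {
      "species": "sp12",
      "gene_a": "g1",
      "gene_b": "g2"
    }
  ],
  "copy_table": {
    "sp01": 1,
    "sp02": 1,
    "sp03": 1,
    "sp04": 1,
    "sp05": 2,
    "sp06": 1,
    "sp07": 1,
    "sp08": 1,
    "sp09": 2,
    "sp10": 1,
    "sp11": 1,
    "sp12": 2
  }
}
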