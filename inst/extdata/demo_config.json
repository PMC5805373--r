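{
  "seed": 1,
  "chrom_len": 1000000,
  "n_genes": 150,
  "n_anchors": 40,
  "n_specific": 60,
  "n_planted_genes": 25,
  "n_random": 5,
  "n_matched_sets": 3,
  "cobinding_prob": 0.95
}
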