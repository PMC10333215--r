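seed: 42
out_dir: demo_out
stages: [simulate, annotate, synteny, matrix]
simulate:
  n_genomes: 3
  n_genes: 40
  n_inversions: 1
  inversion_min: 3
  inversion_max: 8
  loss_prob: 0.03
  pseudo_prob: 0.05
synteny:
  reference: sim01
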