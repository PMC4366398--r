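scenario: two_lesion
two_lesion:
  delta_d: 100.0
  v: 0.001
  n0: 100.0
  n1: 10000.0
  u: 1.0e-05
  d_bar: 50.0
  beta:
  - 0.05
  - 0.5
  alpha:
  - 0.04
  - 0.4
  n_genotypes: 2.0
seed: 1
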