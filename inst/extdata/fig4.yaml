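# Two-lesion metastasis treatment, worst-case drug split (full sanctuary).
scenario: two_lesion
seed: 1
two_lesion:
  delta_d: 100
  v: 1.0e-4
  d_bar: 50
  n0: 1000
  n1: 1.0e+08
  beta: [0.05, 0.5]
  alpha: [0.04, 0.4]
  u: 1.0e-9
  n_genotypes: 2
drug_response:
  ic50: 50
  m: 2
  rho: 5
  s: 0.01
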