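# Onion solid tumor: 30 concentric shells around a central vessel,
# two point mutations needed for full resistance.
scenario: onion
seed: 1
onion:
  inv_tau_d: 1.0
  v: 2.0e-4
  M: 30
  n_genotypes: 3
  n_cells: 1.0e+11
  diameter: 4.6
  tau_g: 1
  tau_c: 1
  D0: 500
  b0: 0.5
  d0: 0.4
  u: 1.0e-9
drug_response:
  ic50: 50
  m: 2
  rho: 5
  s: 0.01
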