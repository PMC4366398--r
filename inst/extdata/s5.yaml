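# 20-compartment ring with a Gaussian drug profile; founder cell in the
# lowest-concentration compartment.
scenario: ring
seed: 1
ring:
  sigma: 24.7
  v: 0.01
  topology: ring
  M: 20
  n_genotypes: 5
  d_bar: 50
  b0: 0.2
  d0: 0.1
  u: 1.0e-4
drug_response:
  ic50: 100
  m: 2
  rho: 1.1
  s: 0.01
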