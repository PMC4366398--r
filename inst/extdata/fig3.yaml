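# Minimal two-compartment, two-genotype model with explicit rates;
# single sensitive founder in the drug-containing compartment.
scenario: custom
seed: 1
rates:
  - {genotype: 0, compartment: 0, birth: 0.1, death: 0.05}
  - {genotype: 0, compartment: 1, birth: 0.38, death: 0.4}
  - {genotype: 1, compartment: 0, birth: 0.099, death: 0.05}
  - {genotype: 1, compartment: 1, birth: 0.5, death: 0.4}
mutation:
  u: 1.0e-4
migration:
  v: 1.0e-2
  topology: pairwise
census:
  - {genotype: 0, compartment: 1, count: 1}
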