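# Demo: small simulated paired BS/oxBS cohort with planted 5mC and 5hmC
# effects, including an anti-correlated (coupled) 5mC/5hmC region.
mode: simulate
seed: 42
simulate:
  n_chromosomes: 2
  cpgs_per_chromosome: 400
  n_case: 10
  n_control: 10
  effects:
    - {mark: 5mC, delta: 0.3, coupling: -0.15, n: 3}
    - {mark: 5hmC, delta: 0.15, coupling: 0, n: 3}
marks: ["5mC", "5hmC", "BS"]
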