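# Cross level-set family at S = 1 (F' = 2, G' = 1), D = 9, no cubic term:
# the quadratic nonlinearity dominates and spots form.
seed: 1
kinetics:
  family: cross
  S: 1
  C: 0
simulation:
  D: 9
  L: 50
  Ly: 50
  nx: 128
  ny: 128
  tMin: 10000
  derivTol: 0.001
  icRange: 0.1
output:
  prefix: spots-C0
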