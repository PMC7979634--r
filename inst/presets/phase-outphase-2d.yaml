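# Phase-switching family on the right branch (a = 6, b = 1): cross kinetics,
# u and v out of phase. 50 x 50 domain, D = 50.
seed: 1
kinetics:
  family: switching
  a: 6
  b: 1
simulation:
  D: 50
  L: 50
  Ly: 50
  nx: 128
  ny: 128
  tMin: 10000
  derivTol: 0.001
  icRange: 0.1
output:
  prefix: phase-outphase
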