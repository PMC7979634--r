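# 1D circular-region system at the origin (a = b = 0): F = 2, G = 1, D = 8.
# L = 3.7 just exceeds the minimum domain Lc ~ 3.77, so no stable pattern
# forms (subcritical domain); compare circle-1d-L3.8.
seed: 1
kinetics:
  family: FG
  F: 2
  G: 1
simulation:
  D: 8
  L: 3.7
  nx: 256
  tMin: 10000
  derivTol: 0.001
  icRange: 0.1
output:
  prefix: circle-1d-L3.7
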