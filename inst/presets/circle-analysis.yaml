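# Linear analysis of the circular parameter region (unit disc),
# F = 2 - a^2, G = 1 + b^2, working diffusion ratio D = 8.
seed: 1
stability:
  region: circle
  D: 8
  resolution: 401
output:
  prefix: circle-analysis
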