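# Linear analysis of the two-branch region (a-3)^2 - b^2 >= 1, a,b > 0,
# restricted to 0 <= a <= 6; D = 50 exceeds the Dc supremum.
seed: 1
stability:
  region: hyperbolic
  D: 50
  resolution: 401
output:
  prefix: hyperbolic-analysis
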