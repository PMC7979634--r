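# Spatiotemporal heterogeneity: C steps from 0 to 2 across x = 60 (tanh,
# width 1) and the two halves swap every 3000 time units (square wave of
# period 6000), so spots and stripes alternate in space and time.
seed: 1
kinetics:
  family: switching
  a: 1
  b: 1
fields:
  - name: C
    type: tanhStep
    axis: x
    center: 60
    width: 1
    low: 0
    high: 2
    period: 6000
    alternate: complement
simulation:
  D: 50
  L: 120
  Ly: 60
  nx: 192
  ny: 96
  tMin: 5900
  tMax: 5900
  derivTol: 0.001
  icRange: 0.1
output:
  prefix: stripe-spot-oscillation
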