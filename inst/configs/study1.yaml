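# Balanced bivariate design; the full study grid crosses
# n in {5, 10, 20}, J in {50, 100, 200, 500, 1000} and ICCs {.10, .30}.
# This file encodes the n = 5, J = 200, small-ICC cell.
population:
  iccs: [0.10, 0.10]
  rho_b: 0.50
  rho_w: 0.20
design:
  J: 200
  "n": 5
  shape: balanced
  interval: 0.0
missing:
  targets: [v1]
  p: 0.25
  lambda: 0.0
methods: [CD, LD, gm, agm, twolevel]
analyses:
  - {model: empty, outcome: v1, parameter: icc, truth: 0.10}
  - {model: latent, predictor: v1, outcome: v2, parameter: beta_b, truth: 0.5}
  - {model: latent, predictor: v2, outcome: v1, parameter: beta_b, truth: 0.5}
  - {model: manifest, predictor: v1, outcome: v2, parameter: gamma_b, truth: cd}
m: 10
iterations: 10
replications: 1000
seed: 1
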