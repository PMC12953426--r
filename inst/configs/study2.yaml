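# Unbalanced designs around an average group size of 10; the grid
# crosses J in {50, 200, 1000}, ICCs {.10, .30} and the four group-size
# shapes U40/U80 (uniform) and B40/B80 (bimodal).  This file encodes
# the U80, J = 200, small-ICC cell with the size-extended methods.
population:
  iccs: [0.10, 0.10]
  rho_b: 0.50
  rho_w: 0.20
design:
  J: 200
  "n": 10
  shape: uniform
  interval: 0.80
missing:
  targets: [v1]
  p: 0.25
  lambda: 0.0
methods: [CD, LD, gm, gm_star, agm, agm_star, twolevel]
analyses:
  - {model: empty, outcome: v1, parameter: icc, truth: 0.10}
  - {model: latent, predictor: v1, outcome: v2, parameter: beta_b, truth: 0.5}
m: 10
iterations: 10
replications: 1000
seed: 2
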