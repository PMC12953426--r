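# Many variables with a homogeneous multilevel structure: K = 25,
# n = 10, common correlation .50 at both levels, missingness on every
# variable; the grid crosses J in {50, 100, 200} and ICCs {.10, .30}.
# This file encodes the J = 50, ICC .10 cell.
population:
  iccs: [0.10, 0.10, 0.10, 0.10, 0.10, 0.10, 0.10, 0.10, 0.10, 0.10,
         0.10, 0.10, 0.10, 0.10, 0.10, 0.10, 0.10, 0.10, 0.10, 0.10,
         0.10, 0.10, 0.10, 0.10, 0.10]
  rho_b: 0.50
  rho_w: 0.50
design:
  J: 50
  "n": 10
  shape: balanced
  interval: 0.0
missing:
  targets: [v1, v2, v3, v4, v5, v6, v7, v8, v9, v10, v11, v12, v13,
            v14, v15, v16, v17, v18, v19, v20, v21, v22, v23, v24, v25]
  p: 0.25
  lambda: 0.0
methods: [CD, gm, agm, twolevel]
analyses:
  - {model: empty, outcome: v1, parameter: icc, truth: 0.10}
  - {model: single, outcome: v1, predictor: v2, parameter: v2, truth: 0.5}
  - {model: single_multi, outcome: v1, parameter: v2, truth: cd}
  - {model: latent, predictor: v2, outcome: v1, parameter: beta_b, truth: 0.5}
m: 10
iterations: 20
replications: 1000
seed: 3
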