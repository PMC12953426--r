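# gmimpute

Multiple imputation for two-level (clustered) data using **single-level
imputation models with group means**.  Instead of the random-intercept
models of conventional multilevel multiple imputation — which become
unstable with many variables, few groups, or weak clustering —
`gmimpute` carries the multilevel structure through observed aggregates:

* **GM**: each incomplete variable is imputed from a single-level
  Bayesian regression that includes the group-mean-centred other
  variables, their group means, and the *target's own group mean*
  \(\bar X_{\bullet j}\) in place of a random intercept;
* **AGM**: the target's own aggregate is the *adjusted* (leave-one-out)
  group mean \(\tilde X_{ij} = \frac{1}{n_j-1}\sum_{i'\ne i} X_{i'j}\),
  which removes the self-dependency of GM (values never help impute
  themselves);
* **GM\*/AGM\***: extensions for unbalanced designs that add a
  group-size term \(w_j = 1/n_j\) and its interactions with all
  group-mean terms;
* **twolevel**: a Gibbs-refreshed random-intercept imputation method as
  the conventional comparator.

All methods run inside one fully-conditional-specification (chained
equations) engine with passive updating: every sweep recomputes group
means, adjusted means and size terms from the currently completed data.

The package also provides the closed-form asymptotic bias of the
non-iterative GM/AGM schemes for a single variable under MCAR — GM
inflates the between-group variance by
\(p\,\frac{n_{obs}+n-1}{(n-1)\,n_{obs}}\,\sigma^2\) (and deflates the
within variance equally), AGM biases run the other way and are scaled
by the reliability \(\gamma = \tau^2/(\tau^2+\sigma^2/(n_{obs}-1))\) —
plus a Monte Carlo oracle validating those formulas, maximum-likelihood
analysis models for clustered data (empty model with ICC, latent and
manifest covariate two-level regressions, cluster-robust single-level
regression), Rubin's pooling rules, and a simulation harness computing
bias, coverage and Monte Carlo standard errors over replications.

## Worked example

```r
library(gmimpute)

# a standardized bivariate two-level population: ICCs .10,
# between-group correlation .50, within-group correlation .20
pop <- make_population(c(0.10, 0.10), rho_b = 0.5, rho_w = 0.2)
dat <- simulate_complete(pop, sizes = rep(5, 200), seed = 1)

# delete 25% of v1 completely at random via the latent-response model
mis <- ampute(dat, missingness_spec("v1", p = 0.25), seed = 2)

# impute with adjusted group means: m = 10 copies, 10 FCS sweeps
imp <- fcs_impute(mis, method = "agm", m = 10, iterations = 10, seed = 3)
imp
#> FCS multiple imputation (agm): m = 10, iterations = 10
#>   imputed variables: v1

# analyze each completed copy and pool with Rubin's rules
fits <- sapply(imp$imputations, function(d) {
  f <- fit_empty(d, "v1")
  c(f$estimates[["icc"]], f$std_errors[["icc"]]^2)
})
pool_rubin(fits[1, ], fits[2, ])
#> Pooled estimate (m = 10): 0.0225
#>   W = 0.00058, B = 0.00050, T = 0.00113, df = 37.94
#>   95% CI: [-0.0455, 0.0905]
```

On this particular draw the complete data give
`fit_empty(dat, "v1")` an ICC of 0.026 (SE 0.024, a low draw from a
population value of 0.10), and the AGM-pooled estimate 0.023 tracks it
closely.  Imputing the same amputed data with `method = "gm"` instead
pools to an ICC of 0.141 — inflated by about 0.11 relative to the
complete-data estimate.  That inflation is the self-dependency failure
mode of the plain group-mean model (values help impute themselves,
manufacturing spurious between-group variance), which the adjusted
group means are designed to remove.

A full simulation condition is one call:

```r
cfg <- study_config(
  population = pop,
  design = group_size_design(J = 200, n = 5),
  missing = missingness_spec("v1", 0.25),
  methods = c("CD", "gm", "agm"),
  analyses = list(
    list(model = "empty", outcome = "v1", parameter = "icc", truth = 0.10),
    list(model = "latent", predictor = "v1", outcome = "v2",
         parameter = "beta_b", truth = 0.5)),
  replications = 300, seed = 42, m = 10, iterations = 10)
run_condition(cfg)
```

Ready-made condition files for the balanced, unbalanced and
many-variable study designs live in `inst/configs/`, and a thin command
line front end (`inst/cli/gmimpute.R`) exposes `impute`, `analyze`,
`pool`, `theory` and `study` subcommands over CSV/YAML/JSON files.

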