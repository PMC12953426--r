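---
title: "Group-mean-based multiple imputation for two-level data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Group-mean-based multiple imputation for two-level data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Clustered designs — pupils in classrooms, patients in clinics, repeated
measures in persons — routinely arrive with sporadically missing values.
Multiple imputation (MI) is the standard remedy, but for two-level data
the imputation model has to respect the variance decomposition

$$
X_{ij} = X^B_j + X^W_{ij}, \qquad
X^B_j \sim N(\mu, \Sigma_B), \quad X^W_{ij} \sim N(0, \Sigma_W),
$$

otherwise downstream multilevel analyses (intraclass correlations,
between- and within-group regression slopes) are distorted.  The
conventional answer is to impute from random-intercept models, but those
multilevel imputation models become fragile exactly where applied work
needs them most: many variables, few groups, and intraclass correlations
(ICCs) near zero.

`gmimpute` implements a family of *single-level* chained-equations
(FCS) imputation methods that carry the multilevel structure through
observed group means instead of random effects:

* **GM** — the imputation model for a target variable includes, besides
  the group-mean-centred other variables and their group means, the
  *target's own group mean* $\bar{X}_{\bullet j}$ in place of a random
  intercept.
* **AGM** — the target's own aggregate is replaced by the *adjusted*
  (leave-one-out) group mean
  $\tilde{X}_{ij} = \tfrac{1}{n_j - 1}\sum_{i' \ne i} X_{i'j}$, so a
  person's imputed value never conditions on their own previous
  imputation.
* **GM\*/AGM\*** — for unbalanced designs, the same models extended
  with a group-size term $w_j = f(n_j)$ (default $1/n_j$) and its
  interactions with every group-mean term, letting the between-group
  relations vary with group size.
* **twolevel** — a conventional random-intercept imputation method
  (Gibbs-refreshed) included as the comparator.

All variants run inside one FCS driver (`fcs_impute()`): missing cells
are initialized by resampling observed values, then each sweep visits
the incomplete variables in column order, *recomputes every derived
term from the currently completed data* (passive updating), draws new
values from the Bayesian posterior predictive of the univariate model,
and writes them back before the next variable is visited.

## Why the adjustment matters

The group mean of $n_j$ values measures the latent between-group
component with reliability $\tau^2 / (\tau^2 + \sigma^2 / n_j)$, so
using it as a predictor is principled.  But the *GM* scheme feeds each
person's own current value back into their own predictor.  For a single
variable in a balanced design with a fixed fraction $p$ of values
missing per group (MCAR), non-iterative versions of the two schemes can
be analysed in closed form (`gm_asymptotic_bias()`,
`agm_asymptotic_bias()`).  GM inflates the between-group variance by

$$
p\,\frac{n_{obs} + n - 1}{(n-1)\,n_{obs}}\,\sigma^2
$$

and deflates the within-group variance by the same amount; AGM's biases
run in the opposite direction, are scaled by the reliability of the
adjusted mean $\gamma = \tau^2/(\tau^2 + \sigma^2/(n_{obs}-1))$, and are
uniformly smaller in magnitude for the between variance across the
grids we assert in the tests.  `noniterative_bias()` is a Monte Carlo
oracle for the same simplified scheme — it simulates, amputes with a
fixed per-group missing count, imputes once with observed-only means,
and estimates the variance components by the balanced closed-form ML
expressions — and the test suite checks formula/oracle agreement to
within three Monte Carlo standard errors.  Note the derivation's
fixed-count, observed-only-means setup is a deliberate simplification
of the iterative engine, so these formulas indicate direction and order
of magnitude rather than the exact bias of `fcs_impute()`.

## Analysis models and pooling

The package ships the four analysis models the simulation harness
evaluates, all fitted by maximum likelihood (not REML, so results are
comparable like-for-like with structural-equation ML fitters commonly
used for these models):

* `fit_empty()` — random-intercept empty model; reports the ICC with a
  delta-method SE from the observed information.  Balanced data use the
  closed-form ML solution; otherwise a bounded quasi-Newton search.
  The between variance is constrained nonnegative here; a boundary hit
  is flagged and yields ICC 0.
* `fit_latent_covariate()` — the saturated bivariate two-level model;
  the latent between-group slope is $\hat\tau_{XY}/\hat\tau_X^2$.
  Following SEM practice, $\Sigma_B$ is *not* constrained positive
  semidefinite: Heywood cases are admitted and flagged.  This choice is
  deliberate — constraining the between variance to a small positive
  floor turns near-boundary samples into enormous slope ratios, whereas
  the unconstrained estimator stays comparable with the reference
  analyses.  The slope's sampling distribution is still heavy-tailed in
  small samples with small ICCs; that is a property of the estimand.
* `fit_manifest_covariate()` — random-intercept regression on the
  group-mean-centred predictor and its manifest group mean (via
  `lme4`, ML).  Its between-group population slope is the attenuated
  $(\tau_{XY} + \sigma_{XY}/n)/(\tau_X^2 + \sigma_X^2/n)$, which is why
  the harness evaluates it against a complete-data reference rather
  than the latent value.
* `fit_single_level()` — OLS with CR1-type cluster-robust standard
  errors ($J/(J-1)\cdot(N-1)/(N-q)$ small-sample factor) and t
  intervals on $J - 1$ degrees of freedom.  Which small-sample flavour
  and reference distribution to use is genuinely open; CR1 with
  $t_{J-1}$ is the common econometric default and is what we document
  and test.

Per-imputation estimates are combined by `pool_rubin()`: classic
Rubin rules with total variance $W + (1 + 1/m)B$ and degrees of freedom
$(m-1)(1 + W/((1+1/m)B))^2$.  The Barnard–Rubin small-sample adjustment
is available as an option but off by default, because the reference
results are pooled with the classic rules.  When all imputations agree
($B = 0$) the interval degenerates to the within-variance normal
interval — a documented branch, not an error.

## The data generator and what it does (not) emulate

`make_population()` builds standardized populations: variable $k$ has
between variance $\tau_k^2 = \mathrm{ICC}_k$ and within variance
$1 - \mathrm{ICC}_k$, with common correlations $\rho_B$, $\rho_W$
applied to the level-specific standard deviations.  ICC 0 variables are
legal (their between row/column is zero).  `simulate_complete()` draws
one between vector per group plus independent within deviations;
`draw_group_sizes()` realizes balanced, uniform, or bimodal group-size
designs.  Uniform sizes cycle deterministically through the integer
grid covering the interval — not resampled — so the size distribution
contributes no extra Monte Carlo noise and the realized mean equals the
nominal average whenever the group count is a multiple of the grid
size.

Missingness is induced by a latent-response (probit-type) model:
$R^*_{ij} = \alpha + \lambda z_{ij} + \delta_{ij}$ with
$\delta \sim N(0, 1-\lambda^2)$ and $\alpha = \Phi^{-1}(p)$ computed
exactly (the commonly quoted $-0.67$ for 25% is the rounded value); a
cell goes missing when $R^* > 0$.  $\lambda = 0$ gives MCAR; $\lambda
\ne 0$ gives MAR in the standardized predictor.  With several target
variables the latent responses are drawn independently per variable —
the natural default in the absence of a specified cross-variable
missingness correlation.

The generator emulates multivariate-normal two-level populations with
homogeneous correlations and sporadic person-level missingness.  It
does not emulate non-normal or categorical data, systematically missing
group-level variables, MNAR mechanisms, random slopes, or three-level
structures — so passing tests here say nothing about those settings.

## Numerical choices

* **Imputation draws.**  The normal draw uses the standard
  noninformative-prior posterior: $\sigma^{*2} = \mathrm{RSS} /
  \chi^2_{n_{obs}-q}$, $\beta^* \sim N(\hat\beta, \sigma^{*2}
  (X'X)^{-1})$.  Exactly collinear columns are detected by pivoted
  Cholesky and dropped (logged in the result); a ridge of $10^{-5}$
  times the mean diagonal is added only when the cross-product matrix
  is numerically ill-conditioned.  Dropping is what makes the starred
  variants usable on balanced data, where $w_j$ is constant and aliased
  with the intercept.
* **Two-level draws.**  One Gibbs refresh of $(u, \beta, \sigma^2,
  \tau^2)$ per FCS visit, with state carried across visits within a
  chain and a short warm start on the first visit.  Priors: flat on
  $\beta$, Jeffreys on $\sigma^2$, and a scaled inverse-$\chi^2$ draw
  with $J-1$ degrees of freedom for $\tau^2$, floored at $10^{-8}$ so
  the chain cannot collapse.  Groups without observed rows draw their
  intercept from $N(0, \tau^2)$.
* **Initialization and visit order.**  Missing cells start as draws
  with replacement from the variable's observed values (in-range by
  construction); variables are visited in column order.  Both are
  determinism-motivated defaults; the FCS literature provides no single
  prescription.
* **Iteration counts.**  User-set, defaulting to 10 sweeps and 10
  imputations; the many-variable configurations use 20 sweeps.  The
  engine exports per-iteration chain means and SDs (`plot()` on the
  result) but applies no automatic stopping rule.
* **Randomness.**  A master seed spawns per-chain, per-replication and
  per-stage substreams through an integer hash (`substream_seed()`), so
  any single replication can be reproduced in isolation and results do
  not depend on execution order.

## The simulation harness

`run_condition()` executes generate → ampute → impute → analyze → pool
over independent replications and reports bias, coverage of nominal 95%
intervals, and Monte Carlo standard errors ($SD/\sqrt{R}$ for bias,
$\sqrt{c(1-c)/R}$ for coverage).  All methods within a replication
share the same generated and amputed data (a paired design — free
variance reduction for method contrasts); a method that fails in a
replication is excluded and counted for that method only.  For
manifest-covariate parameters the reference value is the mean
complete-data estimate over the same replications, since the manifest
estimand differs from the latent population value.

Problem sizes in the bundled tests and the acceptance script are
scaled-down choices we consider adequate for desk-scale verification:
the balanced bivariate cell runs 150–300 replications and the
25-variable heterogeneous-ICC cell 30–100 replications, with Monte
Carlo uncertainty propagated into every comparison; the bundled YAML
configurations document the full 1000-replication conditions.

## Known limitations

* The latent-covariate slope is a ratio estimator; with few groups and
  small ICCs its pooled estimate has heavy tails, and bias summaries
  for it carry wide Monte Carlo error bands.
* The two-level imputation method uses a single Gibbs refresh per
  visit; with very few groups its $\tau^2$ chain mixes slowly, which is
  one reason the comparator — like the multilevel imputation software
  it mirrors — degrades in the many-variable, weak-ICC settings.
* The closed-form bias theory applies to the simplified non-iterative
  schemes; it predicts direction and order of magnitude, not the exact
  bias of the iterative engine.
* Categorical targets, MNAR mechanisms, random slopes, and designs
  deeper than two levels are out of scope.
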