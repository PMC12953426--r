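test_that("the empty model matches closed-form and lme4 ML solutions", {
  pop <- make_population(0.2)
  d <- simulate_complete(pop, rep(10, 80), seed = 1)
  f <- fit_empty(d, "v1")
  # independent route: lme4 maximum likelihood
  lf <- lme4::lmer(v1 ~ 1 + (1 | group), data = d, REML = FALSE)
  vc <- as.data.frame(lme4::VarCorr(lf))
  expect_equal(f$estimates[["tau2"]], vc$vcov[1], tolerance = 1e-5)
  expect_equal(f$estimates[["sigma2"]], vc$vcov[2], tolerance = 1e-6)
  expect_equal(f$estimates[["mu"]], unname(lme4::fixef(lf)[1]),
               tolerance = 1e-6)
  expect_true(all(f$std_errors > 0))

  # unbalanced groups exercise the optimizer path
  du <- simulate_complete(pop, draw_group_sizes(
    group_size_design(60, 10, "uniform", 0.8)), seed = 2)
  fu <- fit_empty(du, "v1")
  lfu <- lme4::lmer(v1 ~ 1 + (1 | group), data = du, REML = FALSE)
  vcu <- as.data.frame(lme4::VarCorr(lfu))
  expect_equal(fu$estimates[["tau2"]], vcu$vcov[1], tolerance = 1e-4)
  expect_equal(fu$estimates[["sigma2"]], vcu$vcov[2], tolerance = 1e-4)
})

test_that("the empty model handles the zero-variance boundary", {
  # all group means equal: the between variance sits at the boundary
  d <- data.frame(group = rep(1:3, each = 2), v1 = c(-1, 1, -2, 2, -3, 3))
  f <- fit_empty(d, "v1")
  expect_equal(f$estimates[["icc"]], 0)
  expect_true(f$extra$boundary)
})

test_that("empty-model ICC is recovered at large J", {
  pop <- make_population(0.2)
  d <- simulate_complete(pop, rep(10, 10000), seed = 3)
  f <- fit_empty(d, "v1")
  expect_lt(abs(f$estimates[["icc"]] - 0.2), 3 * f$std_errors[["icc"]])
})

test_that("the balanced latent-covariate fit equals the moment solution", {
  pop <- study1_population()
  d <- simulate_complete(pop, rep(5, 100), seed = 4)
  f <- fit_latent_covariate(d, "v1", "v2")
  # independent closed-form route from group-level summaries
  J <- 100; n <- 5; N <- J * n
  Z <- cbind(d$v1, d$v2)
  zb <- apply(Z, 2, tapply, d$group, mean)
  SW <- crossprod(Z - zb[d$group, ]) / (N - J)
  V <- crossprod(sweep(zb, 2, colMeans(zb))) / J
  SB <- V - SW / n
  expect_equal(f$estimates[["tau_x2"]], SB[1, 1], tolerance = 1e-10)
  expect_equal(f$estimates[["beta_b"]], SB[1, 2] / SB[1, 1],
               tolerance = 1e-10)
  expect_equal(f$estimates[["beta_w"]], SW[1, 2] / SW[1, 1],
               tolerance = 1e-10)
})

test_that("latent slopes are recovered in balanced and unbalanced designs", {
  pop <- study1_population()
  d <- simulate_complete(pop, rep(10, 10000), seed = 5)
  f <- fit_latent_covariate(d, "v1", "v2")
  expect_lt(abs(f$estimates[["beta_b"]] - 0.5), 3 * f$std_errors[["beta_b"]])
  expect_lt(abs(f$estimates[["beta_w"]] - 0.2), 3 * f$std_errors[["beta_w"]])

  sizes <- draw_group_sizes(group_size_design(2000, 10, "uniform", 0.8))
  du <- simulate_complete(pop, sizes, seed = 6)
  fu <- fit_latent_covariate(du, "v1", "v2")
  expect_true(fu$extra$converged)
  expect_lt(abs(fu$estimates[["beta_b"]] - 0.5),
            3 * fu$std_errors[["beta_b"]])
  expect_lt(abs(fu$estimates[["beta_w"]] - 0.2),
            3 * fu$std_errors[["beta_w"]])
})

test_that("the manifest between slope targets the attenuated quantity", {
  pop <- study1_population()
  n <- 5
  d <- simulate_complete(pop, rep(n, 4000), seed = 7)
  f <- fit_manifest_covariate(d, "v1", "v2")
  gb_true <- manifest_population_slope(0.05, 0.18, 0.10, 0.90, n)
  expect_equal(gb_true, (0.05 + 0.18 / 5) / (0.10 + 0.90 / 5))
  expect_lt(abs(f$estimates[["gamma_b"]] - gb_true),
            3 * f$std_errors[["gamma_b"]])
  # within slope targets sigma_xy / sigma_x2 = 0.2
  expect_lt(abs(f$estimates[["gamma_w"]] - 0.2),
            3 * f$std_errors[["gamma_w"]])
})

test_that("single-level regression is exact on noiseless data and robust", {
  d <- data.frame(group = rep(1:10, each = 3))
  set.seed(8)
  d$v1 <- rnorm(30)
  d$v2 <- 1 + 2 * d$v1
  f <- suppressWarnings(fit_single_level(d, "v2", "v1"))  # perfect fit
  expect_equal(unname(f$estimates), c(1, 2), tolerance = 1e-10)
  expect_equal(unname(f$std_errors), c(0, 0), tolerance = 1e-8)

  # singleton clusters: the CR1-type variance equals HC1
  set.seed(9)
  ds <- data.frame(group = 1:40, v1 = rnorm(40))
  ds$v2 <- 0.5 * ds$v1 + rnorm(40)
  fs <- fit_single_level(ds, "v2", "v1")
  hc <- sandwich::vcovHC(lm(v2 ~ v1, data = ds), type = "HC1")
  expect_equal(unname(fs$std_errors), unname(sqrt(diag(hc))),
               tolerance = 1e-10)
})

test_that("single-level slope recovers the common-correlation truth", {
  # equal correlation .5 at both levels: total slope of v1 on v2 is .5
  pop <- make_population(rep(0.1, 3), rho_b = 0.5, rho_w = 0.5)
  d <- simulate_complete(pop, rep(10, 3000), seed = 10)
  f <- fit_single_level(d, "v1", "v2")
  expect_lt(abs(f$estimates[["v2"]] - 0.5), 3 * f$std_errors[["v2"]])
})

test_that("slope estimates are invariant to shifting the outcome", {
  pop <- study1_population()
  d <- simulate_complete(pop, rep(5, 60), seed = 11)
  d2 <- d
  d2$v2 <- d2$v2 + 7
  for (pair in list(
    c(fit_latent_covariate(d, "v1", "v2")$estimates[["beta_b"]],
      fit_latent_covariate(d2, "v1", "v2")$estimates[["beta_b"]]),
    c(fit_manifest_covariate(d, "v1", "v2")$estimates[["gamma_b"]],
      fit_manifest_covariate(d2, "v1", "v2")$estimates[["gamma_b"]]),
    c(fit_single_level(d, "v2", "v1")$estimates[["v1"]],
      fit_single_level(d2, "v2", "v1")$estimates[["v1"]]))) {
    expect_equal(pair[1], pair[2], tolerance = 1e-6)
  }
})

test_that("listwise deletion drops exactly the incomplete rows", {
  d <- random_clustered(J = 5, sizes = rep(2, 5), seed = 12)
  expect_identical(listwise_delete(d), d)
  d$v1[4] <- NA
  ld <- listwise_delete(d)
  expect_equal(nrow(ld), 9)
  # mask row-sum oracle
  keep <- rowSums(is.na(cbind(d$v1, d$v2))) == 0
  expect_identical(ld, d[keep, ])
  d$v1 <- NA
  expect_error(listwise_delete(d), "every row")
})
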