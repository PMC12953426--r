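test_that("standardized populations carry the intended moments", {
  pop <- make_population(c(0.10, 0.10), rho_b = 0.5, rho_w = 0.2)
  expect_equal(diag(pop$Sigma_B), c(0.10, 0.10))
  expect_equal(diag(pop$Sigma_W), c(0.90, 0.90))
  expect_equal(pop$Sigma_B[1, 2], 0.5 * sqrt(0.10) * sqrt(0.10))
  expect_equal(pop$Sigma_W[1, 2], 0.2 * sqrt(0.90) * sqrt(0.90))
  expect_equal(pop$Sigma_B[1, 2], 0.05)
  expect_equal(pop$Sigma_W[1, 2], 0.18)

  # single variable with between variance .2 / within variance .8
  p1 <- make_population(0.2)
  expect_equal(drop(p1$Sigma_B), 0.2)
  expect_equal(drop(p1$Sigma_W), 0.8)

  # zero-ICC variables: the between block collapses to zero and is PSD
  p0 <- make_population(c(0, 0), rho_b = 0.5)
  expect_true(all(p0$Sigma_B == 0))
})

test_that("non-PSD covariance inputs are rejected with a diagnostic", {
  bad <- matrix(c(1, 2, 2, 1), 2)  # indefinite
  expect_error(two_level_population(c(0, 0), bad, diag(2)),
               "positive semidefinite")
  expect_error(two_level_population(c(0, 0), diag(2), bad),
               "positive semidefinite")
  expect_error(make_population(c(0.5, 0.5), rho_b = 1.5))
})

test_that("group-size designs realize balanced, uniform and bimodal shapes", {
  expect_equal(draw_group_sizes(group_size_design(3, 10)), rep(10L, 3))

  u <- draw_group_sizes(group_size_design(17, 10, "uniform", 0.8))
  expect_equal(sort(unique(u)), 2:18)
  expect_equal(mean(u), 10)  # J is a multiple of the grid size

  b <- draw_group_sizes(group_size_design(4, 10, "bimodal", 0.8))
  expect_equal(sort(b), c(2L, 2L, 18L, 18L))

  expect_error(draw_group_sizes(group_size_design(5, 10, "uniform", 0.95)),
               "below 2")
})

test_that("the generator obeys its degenerate limits", {
  # no within variation: all rows within a group identical
  popW0 <- two_level_population(0, matrix(0.2), matrix(0))
  d <- simulate_complete(popW0, rep(4, 10), seed = 1)
  spread <- tapply(d$v1, d$group, function(v) diff(range(v)))
  expect_true(all(spread == 0))

  # no between variation: variance of group means ~ sigma2 / n
  popB0 <- two_level_population(0, matrix(0), matrix(1))
  J <- 10000; n <- 10
  d <- simulate_complete(popB0, rep(n, J), seed = 2)
  v <- var(tapply(d$v1, d$group, mean))
  mc <- (1 / n) * sqrt(2 / (J - 1))     # SE of a normal variance estimate
  expect_lt(abs(v - 1 / n), 3 * mc)
})

test_that("method-of-moments ICC is recovered at large J", {
  pop <- study1_population()
  J <- 10000; n <- 10
  d <- simulate_complete(pop, rep(n, J), seed = 3)
  gm <- tapply(d$v1, d$group, mean)
  s2 <- mean(tapply(d$v1, d$group, var))       # within variance
  t2 <- var(gm) - s2 / n                       # between variance
  icc <- t2 / (t2 + s2)
  # MC SE of the ICC estimate at this size is well below 0.005
  expect_lt(abs(icc - 0.10), 3 * 0.005)
})

test_that("amputation hits the target rate and respects p = 0", {
  pop <- study1_population()
  d <- simulate_complete(pop, rep(10, 5000), seed = 4)

  d0 <- ampute(d, missingness_spec("v1", 0), seed = 5)
  expect_identical(d0, d)

  p <- 0.25
  dm <- ampute(d, missingness_spec("v1", p), seed = 5)
  N <- nrow(d)
  expect_lt(abs(mean(is.na(dm$v1)) - p), 4 * sqrt(p * (1 - p) / N))
  expect_false(anyNA(dm$v2))
})

test_that("MAR amputation makes missingness increase in the predictor", {
  pop <- study1_population()
  d <- simulate_complete(pop, rep(10, 10000), seed = 6)
  dm <- ampute(d, missingness_spec("v1", 0.25, lambda = 0.5,
                                   predictor = "v2"), seed = 7)
  dec <- cut(d$v2, quantile(d$v2, 0:10 / 10), include.lowest = TRUE)
  rate <- tapply(is.na(dm$v1), dec, mean)
  expect_true(all(diff(rate) > 0))
})

test_that("generation and amputation are seed-deterministic", {
  pop <- study1_population()
  d1 <- simulate_complete(pop, rep(5, 50), seed = 11)
  d2 <- simulate_complete(pop, rep(5, 50), seed = 11)
  expect_identical(d1, d2)
  spec <- missingness_spec("v1", 0.25)
  expect_identical(ampute(d1, spec, seed = 12), ampute(d2, spec, seed = 12))
})

test_that("substreams are reproducible and distinct", {
  expect_identical(substream_seed(1, 2, 3), substream_seed(1, 2, 3))
  s <- c(substream_seed(1, 1), substream_seed(1, 2), substream_seed(2, 1))
  expect_equal(length(unique(s)), 3)
  expect_true(all(s >= 1 & s <= 2147483646))
})
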