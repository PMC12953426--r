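# Fixtures are generated in code; nothing is read from disk.

# the bivariate standardized population used throughout the balanced
# simulation checks: small equal ICCs, contextual effect (rho_B != rho_W)
study1_population <- function(icc = 0.10) {
  make_population(c(icc, icc), rho_b = 0.5, rho_w = 0.2)
}

# small random clustered dataset (complete) for algebraic checks
random_clustered <- function(J = 8, sizes = NULL, seed = 1) {
  set.seed(seed)
  if (is.null(sizes)) sizes <- sample(2:6, J, replace = TRUE)
  g <- rep.int(seq_len(J), sizes)
  data.frame(group = g, v1 = rnorm(length(g)), v2 = rnorm(length(g)))
}

# loop-based (brute force) per-group mean, independent of the package's
# vectorized implementation
loop_group_means <- function(values, group) {
  out <- numeric(length(values))
  for (gg in unique(group)) {
    idx <- which(group == gg)
    out[idx] <- mean(values[idx])
  }
  out
}

loop_adjusted_means <- function(values, group) {
  out <- numeric(length(values))
  for (gg in unique(group)) {
    idx <- which(group == gg)
    for (i in idx) out[i] <- mean(values[setdiff(idx, i)])
  }
  out
}
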