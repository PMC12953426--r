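## Two-level normal populations, group-size designs, data generation and
## amputation.
##
## A population is defined by a mean vector mu and a pair of K x K
## covariance matrices: Sigma_B for the group-level (between) components
## and Sigma_W for the person-level (within) deviations.  A standardized
## population has diag(Sigma_B) + diag(Sigma_W) = 1, so the between
## variances equal the intraclass correlations (ICCs).

.check_psd <- function(S, label, tol = 1e-10) {
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -tol * max(abs(ev), 1)) {
    stop(sprintf("%s is not positive semidefinite (min eigenvalue %.3g)",
                 label, min(ev)), call. = FALSE)
  }
  invisible(TRUE)
}

#' Construct a two-level normal population
#'
#' Builds a two-level population from arbitrary between- and within-group
#' covariance matrices.  For standardized populations prefer
#' [make_population()], which parameterizes the matrices by ICCs and
#' level-specific correlations.
#'
#' @param mu Mean vector (length K).
#' @param Sigma_B Between-group covariance matrix (K x K, PSD).
#' @param Sigma_W Within-group covariance matrix (K x K, PSD).
#' @return An object of class `two_level_population`.
#' @export
two_level_population <- function(mu, Sigma_B, Sigma_W) {
  Sigma_B <- as.matrix(Sigma_B)
  Sigma_W <- as.matrix(Sigma_W)
  K <- length(mu)
  stopifnot(nrow(Sigma_B) == K, ncol(Sigma_B) == K,
            nrow(Sigma_W) == K, ncol(Sigma_W) == K)
  if (max(abs(Sigma_B - t(Sigma_B))) > 1e-12 ||
      max(abs(Sigma_W - t(Sigma_W))) > 1e-12) {
    stop("covariance matrices must be symmetric")
  }
  .check_psd(Sigma_B, "Sigma_B")
  .check_psd(Sigma_W, "Sigma_W")
  structure(list(K = K, mu = as.numeric(mu),
                 Sigma_B = Sigma_B, Sigma_W = Sigma_W),
            class = "two_level_population")
}

#' Standardized two-level population from ICCs and correlations
#'
#' Each variable k has between variance `tau2_k = icc_k` and within
#' variance `sigma2_k = 1 - icc_k`, so the total variance is 1.
#' Off-diagonal elements are `rho_b * tau_k * tau_l` at the between level
#' and `rho_w * sigma_k * sigma_l` at the within level.  A variable with
#' ICC exactly 0 has a zero row/column in the between matrix, which is
#' accepted (the matrix stays PSD).
#'
#' @param iccs Vector of intraclass correlations in `[0, 1)`.
#' @param rho_b Between-group correlation (common to all pairs).
#' @param rho_w Within-group correlation (common to all pairs).
#' @param mu Mean vector or a single value recycled to all variables.
#' @return An object of class `two_level_population`.
#' @examples
#' make_population(c(0.10, 0.10), rho_b = 0.5, rho_w = 0.2)
#' @export
make_population <- function(iccs, rho_b = 0, rho_w = 0, mu = 0) {
  stopifnot(all(iccs >= 0), all(iccs < 1),
            abs(rho_b) <= 1, abs(rho_w) <= 1)
  K <- length(iccs)
  tau <- sqrt(iccs)
  sig <- sqrt(1 - iccs)
  Sigma_B <- rho_b * tcrossprod(tau)
  diag(Sigma_B) <- iccs
  Sigma_W <- rho_w * tcrossprod(sig)
  diag(Sigma_W) <- 1 - iccs
  mu <- rep_len(mu, K)
  two_level_population(mu, Sigma_B, Sigma_W)
}

#' @export
print.two_level_population <- function(x, ...) {
  icc <- diag(x$Sigma_B) / (diag(x$Sigma_B) + diag(x$Sigma_W))
  cat(sprintf("Two-level normal population with %d variable(s)\n", x$K))
  cat("  ICCs:", paste(format(round(icc, 3)), collapse = ", "), "\n")
  invisible(x)
}

#' Describe a group-size design
#'
#' @param J Number of groups (>= 1).
#' @param n Average group size (>= 2).
#' @param shape `"balanced"` (all groups of size n), `"uniform"` (sizes on
#'   an even integer grid over a symmetric interval around n) or
#'   `"bimodal"` (half the groups at each endpoint of that interval).
#' @param interval Half-width of the interval as a fraction of n
#'   (e.g. 0.4, 0.8); ignored for balanced designs.
#' @return An object of class `group_size_design`.
#' @export
group_size_design <- function(J, n, shape = c("balanced", "uniform", "bimodal"),
                              interval = 0) {
  shape <- match.arg(shape)
  stopifnot(is.numeric(J), length(J) == 1, J >= 1,
            is.numeric(n), length(n) == 1, n >= 2,
            is.numeric(interval), length(interval) == 1,
            interval >= 0, interval < 1)
  structure(list(J = as.integer(J), n = n, shape = shape, interval = interval),
            class = "group_size_design")
}

#' Realize group sizes for a design
#'
#' Balanced designs return `n` for every group.  Uniform designs cycle
#' deterministically through the evenly spaced integer grid covering
#' `[n(1 - interval), n(1 + interval)]`, so the realized mean equals `n`
#' exactly whenever `J` is a multiple of the grid size.  Bimodal designs
#' put half the groups at each endpoint of that interval.
#'
#' @param design A [group_size_design()].
#' @param seed Unused; the realization is deterministic by design (kept
#'   for interface symmetry with the other generators).
#' @return Integer vector of `J` group sizes, all `>= 2`.
#' @examples
#' draw_group_sizes(group_size_design(4, 10, "bimodal", 0.8))
#' @export
draw_group_sizes <- function(design, seed = NULL) {
  stopifnot(inherits(design, "group_size_design"))
  J <- design$J
  n <- design$n
  sizes <- switch(design$shape,
    balanced = rep(as.integer(round(n)), J),
    uniform = {
      lo <- as.integer(round(n * (1 - design$interval)))
      hi <- as.integer(round(n * (1 + design$interval)))
      rep_len(seq.int(lo, hi), J)
    },
    bimodal = {
      lo <- as.integer(round(n * (1 - design$interval)))
      hi <- as.integer(round(n * (1 + design$interval)))
      c(rep(lo, floor(J / 2)), rep(hi, ceiling(J / 2)))
    })
  if (any(sizes < 2)) {
    stop("interval produces group sizes below 2; shrink the interval")
  }
  sizes
}

## K x K symmetric matrix square root that tolerates PSD (rank-deficient)
## inputs, e.g. variables with ICC = 0.
.mat_sqrt <- function(S) {
  e <- eigen(S, symmetric = TRUE)
  e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
}

#' Simulate complete clustered data from a two-level population
#'
#' Draws one between-group component vector per group from
#' `N(mu, Sigma_B)` and adds independent within-group deviations from
#' `N(0, Sigma_W)` for every person.
#'
#' @param pop A [two_level_population()].
#' @param sizes Integer vector of group sizes (one per group).
#' @param seed Optional integer seed.
#' @return A data frame with a `group` column followed by variables
#'   `v1`, ..., `vK`; no missing values.
#' @examples
#' pop <- make_population(c(0.1, 0.1), 0.5, 0.2)
#' d <- simulate_complete(pop, rep(5, 20), seed = 1)
#' @export
simulate_complete <- function(pop, sizes, seed = NULL) {
  stopifnot(inherits(pop, "two_level_population"), all(sizes >= 1))
  with_seed(seed, {
    J <- length(sizes)
    N <- sum(sizes)
    K <- pop$K
    LB <- .mat_sqrt(pop$Sigma_B)
    LW <- .mat_sqrt(pop$Sigma_W)
    B <- matrix(rnorm(J * K), J, K) %*% LB
    B <- sweep(B, 2, pop$mu, "+")
    W <- matrix(rnorm(N * K), N, K) %*% LW
    g <- rep.int(seq_len(J), sizes)
    V <- B[g, , drop = FALSE] + W
    colnames(V) <- paste0("v", seq_len(K))
    data.frame(group = g, V)
  })
}

#' Specify a latent-response missingness mechanism
#'
#' Missingness in each target variable is driven by a latent response
#' `R* = alpha + lambda * z + delta`, where `z` is the standardized MAR
#' predictor, `delta ~ N(0, 1 - lambda^2)`, and `alpha = qnorm(p)` so that
#' `P(R* > 0) = p`.  A cell is set missing when its `R*` exceeds 0.
#' `lambda = 0` gives MCAR.  When several targets are listed, their latent
#' responses are drawn independently.
#'
#' @param targets Character vector of target variable names (or integer
#'   indices into the value columns).
#' @param p Intended proportion missing per target, in `[0, 1)`.
#' @param lambda Standardized coefficient of the predictor, `|lambda| <= 1`.
#' @param predictor Name (or index) of the fully observed variable driving
#'   MAR missingness; ignored when `lambda = 0`.
#' @return An object of class `missingness_spec`.
#' @export
missingness_spec <- function(targets, p, lambda = 0, predictor = NULL) {
  stopifnot(p >= 0, p < 1, abs(lambda) <= 1)
  if (lambda != 0 && is.null(predictor)) {
    stop("a predictor is required when lambda != 0")
  }
  if (abs(lambda) == 1) {
    stop("|lambda| = 1 leaves no residual variation in the latent response")
  }
  structure(list(targets = targets, p = p, lambda = lambda,
                 predictor = predictor),
            class = "missingness_spec")
}

.value_cols <- function(data, group = "group") {
  setdiff(names(data), group)
}

.resolve_vars <- function(vars, data, group = "group") {
  vals <- .value_cols(data, group)
  if (is.numeric(vars)) vals[vars] else as.character(vars)
}

#' Induce missing values through the latent-response model
#'
#' @param data Complete clustered data frame (a `group` column plus
#'   numeric variables), e.g. from [simulate_complete()].
#' @param spec A [missingness_spec()].
#' @param seed Optional integer seed.
#' @param group Name of the group identifier column.
#' @return The data frame with target cells set to `NA` where the latent
#'   response exceeded zero.
#' @examples
#' pop <- make_population(c(0.1, 0.1), 0.5, 0.2)
#' d <- simulate_complete(pop, rep(5, 50), seed = 1)
#' dm <- ampute(d, missingness_spec("v1", p = 0.25), seed = 2)
#' mean(is.na(dm$v1))
#' @export
ampute <- function(data, spec, seed = NULL, group = "group") {
  stopifnot(inherits(spec, "missingness_spec"))
  targets <- .resolve_vars(spec$targets, data, group)
  if (!all(targets %in% names(data))) stop("unknown target variable(s)")
  if (spec$p == 0) return(data)
  N <- nrow(data)
  alpha <- qnorm(spec$p)
  z <- 0
  if (spec$lambda != 0) {
    pred <- .resolve_vars(spec$predictor, data, group)
    x <- data[[pred]]
    if (anyNA(x)) stop("MAR predictor must be fully observed")
    z <- (x - mean(x)) / sd(x)
  }
  with_seed(seed, {
    for (v in targets) {
      rstar <- alpha + spec$lambda * z +
        rnorm(N, 0, sqrt(1 - spec$lambda^2))
      data[[v]][rstar > 0] <- NA
    }
  })
  data
}
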