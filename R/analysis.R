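## Analysis models for completed (or complete) clustered data.
##
## All multilevel fits use maximum likelihood (not REML) so that pooled
## results are comparable with structural-equation ML fits of the same
## models.  The empty model and the saturated bivariate two-level model
## are fitted from sufficient statistics with closed-form solutions in
## balanced designs and a bounded quasi-Newton optimizer otherwise;
## standard errors come from the observed information (numerical Hessian
## of the exact log-likelihood), with the delta method for derived
## quantities (ICC, between/within slopes).

.new_fit <- function(estimates, std_errors, extra = list()) {
  structure(list(estimates = estimates, std_errors = std_errors,
                 extra = extra), class = "ml_fit")
}

#' @export
print.ml_fit <- function(x, ...) {
  tab <- cbind(estimate = x$estimates,
               std.error = x$std_errors[names(x$estimates)])
  print(round(tab, 4))
  if (isTRUE(x$extra$boundary)) {
    cat("note: a variance component was estimated at the zero boundary\n")
  }
  invisible(x)
}

#' @export
coef.ml_fit <- function(object, ...) object$estimates

.fit_inputs <- function(data, vars, group) {
  if (anyNA(data[vars])) {
    stop("analysis models require completed data (no NA); ",
         "use listwise_delete() or impute first")
  }
  gi <- .group_index(data[[group]])
  if (length(gi$sizes) < 2) stop("need at least 2 groups")
  gi
}

## --- empty model -----------------------------------------------------------

.empty_stats <- function(y, gi) {
  n_j <- gi$sizes
  J <- length(n_j)
  ybar <- rowsum(y, gi$g)[, 1] / n_j
  ssw <- sum((y - ybar[gi$g])^2)
  list(n_j = n_j, J = J, N = length(y), ybar = ybar, ssw = ssw)
}

## negative log-likelihood in (mu, tau2, sigma2); tau2 may go slightly
## negative during Hessian evaluation as long as all tau2 + sigma2/n_j > 0
.empty_nll <- function(par, st) {
  mu <- par[1]; t2 <- par[2]; s2 <- par[3]
  v <- t2 + s2 / st$n_j
  if (s2 <= 0 || any(v <= 0)) return(1e10)
  0.5 * ((st$N - st$J) * log(s2) + st$ssw / s2 +
           sum(log(v) + (st$ybar - mu)^2 / v) + st$N * log(2 * pi))
}

#' Empty (intercept-only) two-level model with ICC
#'
#' ML estimates of `(mu, tau2, sigma2)` for the random-intercept empty
#' model, with the intraclass correlation `tau2 / (tau2 + sigma2)` and
#' its delta-method standard error.  Balanced designs use the closed-form
#' ML solution; unbalanced designs (or boundary cases) use bounded
#' optimization.  A between-group variance estimated at zero is reported
#' as ICC 0 with a boundary flag.
#'
#' @param data Completed clustered data frame.
#' @param outcome Name of the outcome variable.
#' @param group Name of the group identifier column.
#' @return An `ml_fit` with estimates `mu`, `tau2`, `sigma2`, `icc`.
#' @examples
#' pop <- make_population(0.2, 0, 0)
#' d <- simulate_complete(pop, rep(10, 100), seed = 1)
#' fit_empty(d, "v1")
#' @export
fit_empty <- function(data, outcome, group = "group") {
  gi <- .fit_inputs(data, outcome, group)
  y <- data[[outcome]]
  st <- .empty_stats(y, gi)
  balanced <- length(unique(st$n_j)) == 1
  boundary <- FALSE
  converged <- TRUE
  if (balanced) {
    n <- st$n_j[1]
    mu <- mean(st$ybar)
    s2 <- st$ssw / (st$N - st$J)
    v <- sum((st$ybar - mu)^2) / st$J
    t2 <- v - s2 / n
    par <- c(mu, t2, s2)
  }
  if (!balanced || par[2] < 0) {
    ## moment start, then bounded ML
    mu0 <- mean(y)
    s20 <- st$ssw / (st$N - st$J)
    v0 <- max(var(st$ybar) - s20 * mean(1 / st$n_j), 0)
    opt <- optim(c(mu0, v0, s20), .empty_nll, st = st,
                 method = "L-BFGS-B",
                 lower = c(-Inf, 0, 1e-12),
                 control = list(maxit = 500))
    converged <- opt$convergence == 0
    par <- opt$par
    boundary <- par[2] < 1e-8
    if (boundary) par[2] <- 0
  }
  icc <- par[2] / (par[2] + par[3])
  H <- tryCatch(optimHess(par, .empty_nll, st = st), error = function(e) NULL)
  vc <- NULL
  if (!is.null(H)) {
    vc <- tryCatch(solve(H), error = function(e) MASS::ginv(H))
  }
  se <- rep(NA_real_, 4)
  if (!is.null(vc)) {
    dv <- pmax(diag(vc), 0)
    grad_icc <- c(0, par[3], -par[2]) / (par[2] + par[3])^2
    v_icc <- drop(t(grad_icc) %*% vc %*% grad_icc)
    se <- c(sqrt(dv), sqrt(max(v_icc, 0)))
  }
  est <- c(mu = par[1], tau2 = par[2], sigma2 = par[3], icc = icc)
  names(se) <- names(est)
  .new_fit(est, se,
           list(loglik = -.empty_nll(par, st), converged = converged,
                boundary = boundary, vcov = vc, J = st$J, N = st$N))
}

## --- saturated bivariate two-level model ----------------------------------

.biv_stats <- function(Z, gi) {
  n_j <- gi$sizes
  J <- length(n_j)
  N <- nrow(Z)
  Zbar <- rowsum(Z, gi$g) / n_j
  Wdev <- Z - Zbar[gi$g, , drop = FALSE]
  Wpool <- crossprod(Wdev)
  sizes <- sort(unique(n_j))
  per <- lapply(sizes, function(s) {
    idx <- which(n_j == s)
    zb <- Zbar[idx, , drop = FALSE]
    mns <- colMeans(zb)
    list(n = s, J = length(idx), mean = mns,
         S = crossprod(sweep(zb, 2, mns)))
  })
  list(J = J, N = N, Wpool = Wpool, per = per)
}

## theta = (mu_x, mu_y, tB11, tB12, tB22, sW11, sW12, sW22)
.biv_nll <- function(theta, st) {
  mu <- theta[1:2]
  b11 <- theta[3]; b12 <- theta[4]; b22 <- theta[5]
  w11 <- theta[6]; w12 <- theta[7]; w22 <- theta[8]
  detW <- w11 * w22 - w12^2
  if (w11 <= 0 || detW <= 0) return(1e10)
  Wi <- matrix(c(w22, -w12, -w12, w11), 2) / detW
  nll <- 0.5 * ((st$N - st$J) * log(detW) + sum(Wi * st$Wpool))
  for (p in st$per) {
    v11 <- b11 + w11 / p$n
    v12 <- b12 + w12 / p$n
    v22 <- b22 + w22 / p$n
    detV <- v11 * v22 - v12^2
    if (v11 <= 0 || detV <= 0) return(1e10)
    Vi <- matrix(c(v22, -v12, -v12, v11), 2) / detV
    d <- p$mean - mu
    M <- p$S + p$J * tcrossprod(d)
    nll <- nll + 0.5 * (p$J * log(detV) + sum(Vi * M))
  }
  nll + st$N * log(2 * pi)
}


#' Latent covariate two-level regression (saturated bivariate model)
#'
#' Fits the saturated bivariate two-level normal model by ML and reports
#' the latent between-group slope `beta_b = tau_xy / tau_x2` and the
#' within-group slope `beta_w = sigma_xy / sigma_x2` of the outcome on
#' the predictor, with delta-method standard errors from the observed
#' information of the covariance parameters.
#'
#' As in structural-equation ML fitting of this model, the between-group
#' covariance matrix is *not* constrained to be positive semidefinite:
#' Heywood cases (a negative between-group variance estimate) are
#' admitted and flagged in `$extra$heywood`, so the between-group slope
#' is always the ratio of the unconstrained ML estimates.
#'
#' @param data Completed clustered data frame.
#' @param predictor,outcome Variable names (the slope is
#'   outcome-on-predictor).
#' @param group Name of the group identifier column.
#' @return An `ml_fit` with the six covariance parameters, the two means
#'   and `beta_b`, `beta_w`.
#' @examples
#' pop <- make_population(c(0.1, 0.1), 0.5, 0.2)
#' d <- simulate_complete(pop, rep(10, 200), seed = 1)
#' coef(fit_latent_covariate(d, "v1", "v2"))[c("beta_b", "beta_w")]
#' @export
fit_latent_covariate <- function(data, predictor, outcome, group = "group") {
  gi <- .fit_inputs(data, c(predictor, outcome), group)
  Z <- cbind(data[[predictor]], data[[outcome]])
  st <- .biv_stats(Z, gi)
  balanced <- length(st$per) == 1
  converged <- TRUE
  if (balanced) {
    ## closed-form ML: pooled-within for Sigma_W, group-mean scatter for
    ## V = Sigma_B + Sigma_W / n, Sigma_B by subtraction (unconstrained)
    n <- st$per[[1]]$n
    mu <- st$per[[1]]$mean
    SW <- st$Wpool / (st$N - st$J)
    V <- st$per[[1]]$S / st$J
    SB <- V - SW / n
    theta <- c(mu, SB[1, 1], SB[1, 2], SB[2, 2],
               SW[1, 1], SW[1, 2], SW[2, 2])
  } else {
    ## moment start, then quasi-Newton ML on the natural parameters (the
    ## likelihood returns a large value outside the feasible region,
    ## i.e. when Sigma_W or any Sigma_B + Sigma_W / n_j is not PD)
    SW0 <- st$Wpool / (st$N - st$J)
    mu0 <- Reduce(`+`, lapply(st$per, function(p) p$J * p$mean)) / st$J
    Vall <- Reduce(`+`, lapply(st$per, function(p) {
      d <- p$mean - mu0
      p$S + p$J * tcrossprod(d)
    })) / st$J
    nhar <- st$J / sum(vapply(st$per, function(p) p$J / p$n, numeric(1)))
    SB0 <- Vall - SW0 / nhar
    par0 <- c(mu0, SB0[1, 1], SB0[1, 2], SB0[2, 2],
              SW0[1, 1], SW0[1, 2], SW0[2, 2])
    opt <- optim(par0, .biv_nll, st = st, method = "BFGS",
                 control = list(maxit = 500, reltol = 1e-12))
    converged <- opt$convergence == 0
    theta <- opt$par
  }
  names(theta) <- c("mu_x", "mu_y", "tau_x2", "tau_xy", "tau_y2",
                    "sigma_x2", "sigma_xy", "sigma_y2")
  beta_b <- if (abs(theta["tau_x2"]) > 1e-12) {
    unname(theta["tau_xy"] / theta["tau_x2"])
  } else NA_real_
  beta_w <- unname(theta["sigma_xy"] / theta["sigma_x2"])
  H <- tryCatch(optimHess(theta, .biv_nll, st = st), error = function(e) NULL)
  vc <- if (!is.null(H)) {
    tryCatch(solve(H), error = function(e) MASS::ginv(H))
  }
  se <- rep(NA_real_, 10)
  if (!is.null(vc)) {
    se[1:8] <- sqrt(pmax(diag(vc), 0))
    if (!is.na(beta_b)) {
      gb <- numeric(8)
      gb[3] <- -theta["tau_xy"] / theta["tau_x2"]^2
      gb[4] <- 1 / theta["tau_x2"]
      se[9] <- sqrt(max(drop(t(gb) %*% vc %*% gb), 0))
    }
    gw <- numeric(8)
    gw[6] <- -theta["sigma_xy"] / theta["sigma_x2"]^2
    gw[7] <- 1 / theta["sigma_x2"]
    se[10] <- sqrt(max(drop(t(gw) %*% vc %*% gw), 0))
  }
  est <- c(theta, beta_b = beta_b, beta_w = beta_w)
  names(se) <- names(est)
  .new_fit(est, se,
           list(loglik = -.biv_nll(theta, st), converged = converged,
                heywood = theta[["tau_x2"]] < 0 || theta[["tau_y2"]] < 0,
                boundary = FALSE, vcov = vc, J = st$J, N = st$N))
}

## --- manifest covariate model ----------------------------------------------

#' Manifest covariate two-level regression
#'
#' Random-intercept linear mixed model of the outcome on the group-mean
#' centered predictor and the manifest group mean of the predictor,
#' fitted by ML through \pkg{lme4}.  The between-group slope here targets
#' the attenuated population quantity
#' `(tau_xy + sigma_xy / n) / (tau_x2 + sigma_x2 / n)` in balanced
#' designs, not the latent slope.
#'
#' @inheritParams fit_latent_covariate
#' @return An `ml_fit` with `gamma_b`, `gamma_w` (and intercept), their
#'   standard errors, and the variance components in `$extra`.
#' @export
fit_manifest_covariate <- function(data, predictor, outcome,
                                   group = "group") {
  .fit_inputs(data, c(predictor, outcome), group)
  x <- data[[predictor]]
  g <- data[[group]]
  dd <- data.frame(y = data[[outcome]],
                   xw = within_center(x, g),
                   xb = group_means(x, g),
                   g = g)
  fit <- lme4::lmer(y ~ xw + xb + (1 | g), data = dd, REML = FALSE,
                    control = lme4::lmerControl(calc.derivs = FALSE,
                                                check.conv.singular = "ignore"))
  fe <- lme4::fixef(fit)
  se <- unname(sqrt(diag(as.matrix(vcov(fit)))))
  vcomp <- as.data.frame(lme4::VarCorr(fit))
  tau2 <- vcomp$vcov[vcomp$grp == "g"]
  sigma2 <- vcomp$vcov[vcomp$grp == "Residual"]
  est <- c(intercept = unname(fe[1]), gamma_w = unname(fe["xw"]),
           gamma_b = unname(fe["xb"]))
  ses <- setNames(se[1:3], names(est))
  .new_fit(est, ses,
           list(tau2 = tau2, sigma2 = sigma2,
                loglik = as.numeric(stats::logLik(fit)),
                converged = length(fit@optinfo$conv$lme4$messages) == 0,
                boundary = lme4::isSingular(fit),
                J = length(unique(g)), N = nrow(dd)))
}

## --- single-level regression with cluster-robust SEs ------------------------

#' Single-level regression with cluster-robust standard errors
#'
#' Ordinary least squares of the outcome on the predictors, with
#' CR1-type cluster-robust (sandwich) standard errors clustered on the
#' group — small-sample factor `J/(J-1) * (N-1)/(N-q)` — and a t
#' reference with `J - 1` degrees of freedom for confidence intervals.
#'
#' @param data Completed clustered data frame.
#' @param outcome Outcome variable name.
#' @param predictors Character vector of predictor names.
#' @param group Name of the group identifier column.
#' @param cluster_robust If `FALSE`, report the conventional OLS
#'   standard errors instead.
#' @return An `ml_fit` with one coefficient per predictor (plus
#'   intercept); `$extra$df` holds the CI degrees of freedom.
#' @export
fit_single_level <- function(data, outcome, predictors, group = "group",
                             cluster_robust = TRUE) {
  .fit_inputs(data, c(outcome, predictors), group)
  J <- length(unique(data[[group]]))
  fml <- stats::reformulate(predictors, response = outcome)
  fit <- lm(fml, data = data)
  q <- length(coef(fit))
  if (cluster_robust) {
    if (J < q) {
      warning("fewer clusters than coefficients; ",
              "the robust variance is rank deficient")
    }
    vc <- sandwich::vcovCL(fit, cluster = data[[group]], type = "HC1")
    df <- J - 1
  } else {
    vc <- vcov(fit)
    df <- fit$df.residual
  }
  est <- coef(fit)
  se <- sqrt(diag(vc))
  .new_fit(est, se,
           list(df = df, vcov = vc, cluster_robust = cluster_robust,
                converged = TRUE, boundary = FALSE, J = J, N = nrow(data)))
}

#' Listwise deletion
#'
#' Drops every row with a missing value among the analysis variables;
#' groups that lose all rows disappear.
#'
#' @param data Clustered data frame.
#' @param vars Variables to screen (default: all value columns).
#' @param group Name of the group identifier column.
#' @return The row-subset data frame.
#' @export
listwise_delete <- function(data, vars = NULL, group = "group") {
  if (is.null(vars)) vars <- .value_cols(data, group)
  keep <- complete.cases(data[vars])
  if (!any(keep)) stop("listwise deletion removed every row")
  data[keep, , drop = FALSE]
}
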