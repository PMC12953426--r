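## The FCS imputation engine.
##
## Each incomplete variable gets a univariate imputation model.  The GM
## and AGM families are single-level Bayesian normal regressions whose
## predictors include group means of the other variables and the group
## mean (GM) or leave-one-out adjusted group mean (AGM) of the target
## itself; the starred variants add group-size terms and their
## interactions with the group-mean terms for unbalanced designs.  The
## two-level method replaces the target's aggregate with a random
## intercept updated by a Gibbs refresh at every visit.  All derived
## terms are recomputed from the currently completed data at every visit
## (passive updating).

#' Build a univariate imputation-model specification
#'
#' @param approach One of `"gm"`, `"agm"`, `"gm_star"`, `"agm_star"`,
#'   `"twolevel"`.
#' @param target Name of the target variable.
#' @param others Character vector with the names of the other variables
#'   (at least one).
#' @param size_transform Function of the group sizes used for the starred
#'   variants, default reciprocal.
#' @return An object of class `uni_spec` describing the predictor terms.
#' @examples
#' build_spec("agm", "v1", "v2")
#' @export
build_spec <- function(approach = c("gm", "agm", "gm_star", "agm_star",
                                    "twolevel"),
                       target, others, size_transform = function(n) 1 / n) {
  approach <- match.arg(approach)
  stopifnot(length(target) == 1, length(others) >= 1)
  if (target %in% others) stop("target cannot be one of its own predictors")
  base <- c("(Intercept)",
            paste0("wc.", others),
            paste0("gm.", others))
  own <- switch(approach,
    gm = , gm_star = paste0("gm.", target),
    agm = , agm_star = paste0("agm.", target),
    twolevel = character(0))
  star <- character(0)
  if (approach %in% c("gm_star", "agm_star")) {
    star <- c("w", paste0("w:gm.", others), paste0("w:", own))
  }
  structure(list(approach = approach, target = target, others = others,
                 method = if (approach == "twolevel") "twolevel" else "norm",
                 size_transform = size_transform,
                 terms = c(base, own, star)),
            class = "uni_spec")
}

#' @export
print.uni_spec <- function(x, ...) {
  cat(sprintf("Imputation model for '%s' (%s, %s):\n  %s\n",
              x$target, x$approach, x$method,
              paste(x$terms, collapse = " + ")))
  invisible(x)
}

#' Design matrix for a univariate imputation model
#'
#' Constructs the predictor matrix implied by a [build_spec()]
#' specification from (currently completed) data.  The adjusted group
#' mean of the target is computed excluding each row's own value, so a
#' person's design row never contains their own value of the target.
#'
#' @param spec A `uni_spec`.
#' @param data Completed data frame (no missing values among the
#'   variables used by `spec`).
#' @param group Name of the group identifier column.
#' @return Numeric matrix with one named column per term.
#' @export
build_design <- function(spec, data, group = "group") {
  gi <- .group_index(data[[group]])
  V <- as.matrix(data[c(spec$others, spec$target)])
  .design_matrix(spec, V, gi)
}

## Internal design construction from a value matrix whose columns are
## named; gi is a .group_index() result for the rows.  Fills a
## preallocated matrix whose column order matches spec$terms.
.design_matrix <- function(spec, V, gi) {
  g <- gi$g
  sizes <- gi$sizes
  oi <- match(spec$others, colnames(V))
  ti <- match(spec$target, colnames(V))
  if (anyNA(c(oi, ti))) stop("spec refers to unknown variables")
  no <- length(oi)
  N <- nrow(V)
  GMj <- rowsum(V, g) / sizes
  GM <- GMj[g, , drop = FALSE]
  own <- spec$approach != "twolevel"
  star <- spec$approach %in% c("gm_star", "agm_star")
  q <- 1 + 2 * no + own + if (star) 2 + no else 0
  X <- matrix(1, N, q)
  X[, 1 + seq_len(no)] <- V[, oi, drop = FALSE] - GM[, oi, drop = FALSE]
  X[, 1 + no + seq_len(no)] <- GM[, oi, drop = FALSE]
  cix <- 1 + 2 * no
  if (own) {
    cix <- cix + 1
    if (spec$approach %in% c("gm", "gm_star")) {
      X[, cix] <- GM[, ti]
    } else {
      if (any(sizes < 2)) {
        stop("adjusted group means require all group sizes >= 2")
      }
      X[, cix] <- (sizes[g] * GM[, ti] - V[, ti]) / (sizes[g] - 1)
    }
  }
  if (star) {
    w <- spec$size_transform(sizes)
    if (any(!is.finite(w))) stop("size transform undefined at a group size")
    wrow <- w[g]
    X[, cix + 1] <- wrow
    X[, cix + 1 + seq_len(no)] <-
      wrow * X[, 1 + no + seq_len(no), drop = FALSE]
    X[, cix + 2 + no] <- wrow * X[, cix]
  }
  colnames(X) <- spec$terms
  X
}

#' Bayesian normal-regression imputation draw
#'
#' One proper draw from the posterior predictive distribution of the
#' missing values under the normal linear model with the conventional
#' noninformative prior: draw `sigma*^2 = RSS / chisq(n_obs - q)`, then
#' `beta* ~ N(beta_hat, sigma*^2 (X'X)^-1)`, then missing values as
#' `X_mis beta* + sigma* z`.  Rank-deficient predictor columns are
#' dropped; a small ridge is applied only when the cross-product matrix
#' is numerically ill-conditioned.
#'
#' @param y Numeric vector with the target values (entries at `mis` may
#'   be arbitrary).
#' @param X Design matrix for all rows.
#' @param obs,mis Integer (or logical) indices of observed and missing
#'   rows.
#' @param ridge Ridge factor applied to the normalized cross-product
#'   matrix when ill-conditioned.
#' @return List with `values` (draws for `mis`, in order) and `dropped`
#'   (names of any columns removed for rank deficiency).
#' @export
norm_draw <- function(y, X, obs, mis, ridge = 1e-5) {
  Xo <- X[obs, , drop = FALSE]
  yo <- y[obs]
  dropped <- character(0)
  XtX <- crossprod(Xo)
  ## rank check via pivoted Cholesky (cheaper than a full QR per visit);
  ## exactly dependent columns are dropped, near-collinear ones ridged
  chp <- suppressWarnings(chol(XtX, pivot = TRUE))
  rk <- attr(chp, "rank")
  if (rk < ncol(Xo)) {
    keep <- sort(attr(chp, "pivot")[seq_len(rk)])
    dropped <- colnames(Xo)[-keep]
    if (is.null(dropped)) {
      dropped <- paste0("col", setdiff(seq_len(ncol(Xo)), keep))
    }
    Xo <- Xo[, keep, drop = FALSE]
    X <- X[, keep, drop = FALSE]
    XtX <- crossprod(Xo)
  }
  q <- ncol(Xo)
  no <- nrow(Xo)
  if (no <= q) stop("too few observed rows to fit the imputation model")
  ch <- tryCatch(chol(XtX), error = function(e) NULL)
  if (is.null(ch) ||
      any(diag(ch) < sqrt(.Machine$double.eps) * max(diag(ch)))) {
    XtX <- XtX + ridge * mean(diag(XtX)) * diag(q)
    ch <- chol(XtX)
  }
  bhat <- backsolve(ch, forwardsolve(t(ch), crossprod(Xo, yo)))
  rss <- sum((yo - Xo %*% bhat)^2)
  s2 <- rss / rchisq(1, no - q)
  bstar <- bhat + sqrt(s2) * backsolve(ch, rnorm(q))
  nmis <- if (is.logical(mis)) sum(mis) else length(mis)
  vals <- if (nmis == 0) numeric(0) else
    drop(X[mis, , drop = FALSE] %*% bstar) + sqrt(s2) * rnorm(nmis)
  list(values = vals, dropped = dropped, sigma2 = s2, beta = drop(bstar))
}

## One Gibbs refresh of (u, beta, sigma2, tau2) for the random-intercept
## model, conditional on observed rows.  Priors: flat on beta, Jeffreys on
## sigma2, scaled inverse-chi^2 draw for tau2 with df J - 1.
.gibbs_refresh <- function(yo, Xo, go, n_obs_j, J, state, tau2_floor) {
  r <- yo - drop(Xo %*% state$beta)
  sums <- numeric(J)
  tmp <- rowsum(r, go)
  sums[as.integer(rownames(tmp))] <- tmp[, 1]
  prec <- n_obs_j / state$sigma2 + 1 / state$tau2
  u <- rnorm(J, mean = (sums / state$sigma2) / prec, sd = sqrt(1 / prec))
  ystar <- yo - u[go]
  XtX <- crossprod(Xo)
  ch <- chol(XtX + 1e-10 * mean(diag(XtX)) * diag(ncol(Xo)))
  bhat <- backsolve(ch, forwardsolve(t(ch), crossprod(Xo, ystar)))
  beta <- bhat + sqrt(state$sigma2) * backsolve(ch, rnorm(ncol(Xo)))
  res <- ystar - drop(Xo %*% beta)
  sigma2 <- sum(res^2) / rchisq(1, length(yo))
  tau2 <- max(sum(u^2) / rchisq(1, max(J - 1, 1)), tau2_floor)
  list(beta = drop(beta), u = u, sigma2 = sigma2, tau2 = tau2)
}

#' Random-intercept (two-level) imputation draw
#'
#' One Gibbs refresh of the random-intercept normal model
#' `y = X beta + u_j + e` on the observed rows, followed by a draw of the
#' missing values from the implied posterior predictive.  The sampler
#' state is carried across FCS visits through the `state` argument;
#' groups with no observed rows receive `u_j ~ N(0, tau2)`.  A small
#' positive floor keeps the between-group variance chain away from zero.
#'
#' @inheritParams norm_draw
#' @param group Group identifier per row.
#' @param state Sampler state from the previous visit, or `NULL` to
#'   initialize from least squares.
#' @param tau2_floor Lower floor for the between-group variance draw.
#' @return List with `values`, `state` (pass back on the next visit) and
#'   `dropped`.
#' @export
twolevel_draw <- function(y, X, group, obs, mis, state = NULL,
                          tau2_floor = 1e-8) {
  gi <- .group_index(group)
  J <- length(gi$sizes)
  if (J < 2) stop("two-level imputation requires at least 2 groups")
  Xo <- X[obs, , drop = FALSE]
  yo <- y[obs]
  go <- gi$g[obs]
  qrX <- qr(Xo)
  dropped <- character(0)
  if (qrX$rank < ncol(Xo)) {
    keep <- sort(qrX$pivot[seq_len(qrX$rank)])
    dropped <- colnames(Xo)[-keep]
    Xo <- Xo[, keep, drop = FALSE]
    X <- X[, keep, drop = FALSE]
    qrX <- qr(Xo)
  }
  if (nrow(Xo) <= ncol(Xo)) {
    stop("too few observed rows to fit the imputation model")
  }
  n_obs_j <- tabulate(go, J)
  if (is.null(state) || length(state$beta) != ncol(Xo)) {
    beta <- qr.coef(qrX, yo)
    beta[is.na(beta)] <- 0
    r <- yo - drop(Xo %*% beta)
    sigma2 <- max(var(r), 1e-8)
    has <- n_obs_j > 0
    rbar <- numeric(J)
    tmp <- rowsum(r, go)
    rbar[as.integer(rownames(tmp))] <- tmp[, 1]
    rbar <- rbar / pmax(n_obs_j, 1)
    tau2 <- max(var(rbar[has]) - sigma2 / mean(n_obs_j[has]),
                0.05 * sigma2, tau2_floor)
    state <- list(beta = beta, u = numeric(J), sigma2 = sigma2, tau2 = tau2)
    for (i in 1:2) {  # short warm-up on first visit
      state <- .gibbs_refresh(yo, Xo, go, n_obs_j, J, state, tau2_floor)
    }
  }
  state <- .gibbs_refresh(yo, Xo, go, n_obs_j, J, state, tau2_floor)
  nmis <- if (is.logical(mis)) sum(mis) else length(mis)
  gm_mis <- gi$g[mis]
  vals <- if (nmis == 0) numeric(0) else
    drop(X[mis, , drop = FALSE] %*% state$beta) + state$u[gm_mis] +
      sqrt(state$sigma2) * rnorm(nmis)
  list(values = vals, state = state, dropped = dropped)
}

#' Multiple imputation by chained equations with group-mean models
#'
#' Runs `m` independent FCS chains.  Missing cells are initialized by
#' resampling the variable's observed values; each sweep then visits the
#' incomplete variables in column order, rebuilds that model's derived
#' terms (group means, adjusted group means, size terms) from the
#' currently completed data, draws new imputations, and writes them back
#' before moving on.  Observed cells are never modified.
#'
#' @param data Data frame with a group identifier column and numeric
#'   variables; missing cells are `NA`.
#' @param method Imputation approach: `"gm"`, `"agm"`, `"gm_star"`,
#'   `"agm_star"` or `"twolevel"`.
#' @param m Number of imputations (chains).
#' @param iterations FCS sweeps per chain.
#' @param seed Optional integer seed; chains use independent substreams.
#' @param group Name of the group identifier column.
#' @param size_transform Group-size transform for the starred variants.
#' @return An object of class `gm_mids` holding the `m` completed data
#'   sets (`$imputations`), per-iteration chain means and SDs of the
#'   imputed values (`$chain_mean`, `$chain_sd`) and a log of any
#'   predictor columns dropped for rank deficiency (`$dropped`).
#' @seealso [completed_data()], [pool_rubin()]
#' @examples
#' pop <- make_population(c(0.1, 0.1), 0.5, 0.2)
#' d <- ampute(simulate_complete(pop, rep(5, 50), seed = 1),
#'             missingness_spec("v1", 0.25), seed = 2)
#' imp <- fcs_impute(d, "agm", m = 2, iterations = 3, seed = 3)
#' imp
#' @export
fcs_impute <- function(data, method = c("gm", "agm", "gm_star", "agm_star",
                                        "twolevel"),
                       m = 10, iterations = 10, seed = NULL,
                       group = "group", size_transform = function(n) 1 / n) {
  method <- match.arg(method)
  stopifnot(m >= 1, iterations >= 1)
  vars <- .value_cols(data, group)
  if (length(vars) < 2) stop("need at least two variables")
  V <- as.matrix(data[vars])
  if (!is.numeric(V)) stop("all variables must be numeric")
  gi <- .group_index(data[[group]])
  M <- !is.na(V)
  incomplete <- vars[colSums(!M) > 0]
  cl <- match.call()
  if (length(incomplete) == 0) {
    return(structure(list(call = cl, data = data, method = method, m = m,
                          iterations = iterations, seed = seed,
                          incomplete = character(0),
                          imputations = replicate(m, data, simplify = FALSE),
                          chain_mean = NULL, chain_sd = NULL,
                          dropped = character(0)),
                     class = "gm_mids"))
  }
  if (method %in% c("agm", "agm_star") && any(gi$sizes < 2)) {
    stop("adjusted group means require all group sizes >= 2")
  }
  specs <- lapply(incomplete, function(k) {
    build_spec(method, k, setdiff(vars, k), size_transform)
  })
  names(specs) <- incomplete
  nI <- length(incomplete)
  chain_mean <- array(NA_real_, c(iterations, nI, m),
                      dimnames = list(NULL, incomplete, NULL))
  chain_sd <- chain_mean
  dropped <- character(0)
  imputations <- vector("list", m)
  for (chain in seq_len(m)) {
    cseed <- if (is.null(seed)) NULL else substream_seed(seed, chain)
    with_seed(cseed, {
      Vc <- V
      for (k in incomplete) {
        misk <- !M[, k]
        Vc[misk, k] <- sample(V[M[, k], k], sum(misk), replace = TRUE)
      }
      states <- vector("list", nI)
      names(states) <- incomplete
      for (t in seq_len(iterations)) {
        for (k in incomplete) {
          spec <- specs[[k]]
          misk <- which(!M[, k])
          obsk <- which(M[, k])
          if (spec$method == "twolevel") {
            X <- .design_matrix(spec, Vc, gi)
            res <- twolevel_draw(Vc[, k], X, data[[group]], obsk, misk,
                                 state = states[[k]])
            states[[k]] <- res$state
          } else {
            X <- .design_matrix(spec, Vc, gi)
            res <- norm_draw(Vc[, k], X, obsk, misk)
          }
          Vc[misk, k] <- res$values
          dropped <- union(dropped, res$dropped)
          chain_mean[t, k, chain] <- mean(res$values)
          chain_sd[t, k, chain] <- sd(res$values)
        }
      }
      out <- data
      out[vars] <- as.data.frame(Vc)
      imputations[[chain]] <- out
    })
  }
  structure(list(call = cl, data = data, method = method, m = m,
                 iterations = iterations, seed = seed,
                 incomplete = incomplete, imputations = imputations,
                 chain_mean = chain_mean, chain_sd = chain_sd,
                 dropped = dropped),
            class = "gm_mids")
}

#' Extract a completed data set from a `gm_mids` object
#'
#' @param x A [fcs_impute()] result.
#' @param i Which imputation to return (1..m).
#' @return A completed data frame.
#' @export
completed_data <- function(x, i = 1) {
  stopifnot(inherits(x, "gm_mids"), i >= 1, i <= x$m)
  x$imputations[[i]]
}

#' @export
print.gm_mids <- function(x, ...) {
  cat(sprintf("FCS multiple imputation (%s): m = %d, iterations = %d\n",
              x$method, x$m, x$iterations))
  if (length(x$incomplete)) {
    cat("  imputed variables:", paste(x$incomplete, collapse = ", "), "\n")
  } else {
    cat("  input was complete; returned verbatim copies\n")
  }
  if (length(x$dropped)) {
    cat("  dropped (rank-deficient) columns:",
        paste(x$dropped, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
summary.gm_mids <- function(object, ...) {
  print(object)
  if (length(object$incomplete)) {
    nmis <- sapply(object$incomplete, function(k) sum(is.na(object$data[[k]])))
    cat("  missing cells per variable:\n")
    print(nmis)
  }
  invisible(object)
}

#' Trace plot of the imputation chains
#'
#' Plots the per-iteration mean of the imputed values for each chain, one
#' panel per imputed variable, for eyeballing convergence of the FCS
#' algorithm.
#'
#' @param x A `gm_mids` object.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.gm_mids <- function(x, ...) {
  if (is.null(x$chain_mean)) {
    message("nothing to plot: input was complete")
    return(invisible(x))
  }
  nv <- dim(x$chain_mean)[2]
  op <- par(mfrow = c(nv, 1), mar = c(3, 4, 2, 1))
  on.exit(par(op))
  for (k in seq_len(nv)) {
    matplot(x$chain_mean[, k, ], type = "l", lty = 1,
            xlab = "iteration", ylab = "mean of imputed values",
            main = dimnames(x$chain_mean)[[2]][k], ...)
  }
  invisible(x)
}
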