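## Closed-form theory for the non-iterative GM and AGM imputation
## schemes: group-mean reliability, the manifest population slope, and
## the asymptotic (J -> infinity) biases of the between- and within-group
## variance estimates under MCAR with a fixed per-group missing count,
## plus a Monte Carlo oracle that validates the formulas by simulation.

#' Reliability of the manifest group mean
#'
#' `tau2 / (tau2 + sigma2 / n)`: how well the observed group mean of `n`
#' values measures the latent between-group component.
#'
#' @param tau2 Between-group variance (>= 0).
#' @param sigma2 Within-group variance (> 0).
#' @param n Group size.
#' @return Reliability in `[0, 1)`.
#' @examples
#' group_mean_reliability(0.2, 0.8, 4)
#' @export
group_mean_reliability <- function(tau2, sigma2, n) {
  stopifnot(tau2 >= 0, sigma2 > 0, n >= 1)
  tau2 / (tau2 + sigma2 / n)
}

#' Population between-group slope of the manifest covariate model
#'
#' In a balanced design with groups of size `n`, regressing the outcome
#' on the observed group mean of the predictor targets
#' `(tau_xy + sigma_xy / n) / (tau_x2 + sigma_x2 / n)` — the latent
#' between-group slope attenuated by the unreliability of the group
#' means.
#'
#' @param tau_xy,sigma_xy Between- and within-group covariances.
#' @param tau_x2,sigma_x2 Between- and within-group variances of the
#'   predictor.
#' @param n Group size.
#' @return The manifest between-group population slope.
#' @examples
#' manifest_population_slope(0.05, 0.18, 0.10, 0.90, 5)
#' @export
manifest_population_slope <- function(tau_xy, sigma_xy, tau_x2, sigma_x2, n) {
  stopifnot(tau_x2 + sigma_x2 / n > 0)
  (tau_xy + sigma_xy / n) / (tau_x2 + sigma_x2 / n)
}

#' Asymptotic bias of the non-iterative GM imputation scheme
#'
#' For a single variable in a balanced design with `n_mis = n - n_obs`
#' values per group missing completely at random and imputed once from a
#' regression on the observed-only group mean, the large-J bias of the ML
#' variance components is `+p (n_obs + n - 1) / ((n - 1) n_obs) sigma2`
#' for the between-group variance and its negative for the within-group
#' variance.
#'
#' @param p Proportion missing per group, `0 <= p < 1`.
#' @param n Group size (>= 2).
#' @param n_obs Observed values per group (default `n (1 - p)`).
#' @param sigma2 True within-group variance.
#' @return Named vector `c(tau2 = ..., sigma2 = ...)` of biases.
#' @examples
#' gm_asymptotic_bias(0.25, 8, 6, 0.8)
#' @export
gm_asymptotic_bias <- function(p, n, n_obs = n * (1 - p), sigma2 = 1) {
  stopifnot(p >= 0, p < 1, n >= 2, n_obs >= 1)
  b <- p * (n_obs + n - 1) / ((n - 1) * n_obs) * sigma2
  c(tau2 = b, sigma2 = -b)
}

#' Asymptotic bias of the non-iterative AGM imputation scheme
#'
#' As [gm_asymptotic_bias()], but for imputation from observed-only
#' adjusted (leave-one-out) group means.  The bias is scaled by the
#' reliability of the adjusted group mean
#' `gamma = tau2 / (tau2 + sigma2 / (n_obs - 1))`; it is negative for the
#' between-group variance and positive for the within-group variance.
#'
#' @inheritParams gm_asymptotic_bias
#' @param n_mis Missing values per group (default `n - n_obs`).
#' @param tau2 True between-group variance.
#' @return Named vector `c(tau2 = ..., sigma2 = ...)` of biases.
#' @examples
#' agm_asymptotic_bias(0.25, 8, 6, 2, 0.2, 0.8)
#' @export
agm_asymptotic_bias <- function(p, n, n_obs = n * (1 - p), n_mis = n - n_obs,
                                tau2 = 0, sigma2 = 1) {
  stopifnot(p >= 0, p < 1, n >= 2)
  if (n_obs < 2) stop("the adjusted group mean needs n_obs >= 2")
  gam <- tau2 / (tau2 + sigma2 / (n_obs - 1))
  bt <- -p * (n_mis + (n_mis - 1) / n_obs * gam + 1) /
    ((n - 1) * (n_obs - 1)) * gam * sigma2
  bs <- p * (n_mis - gam + 1) / ((n - 1) * (n_obs - 1)) * gam * sigma2
  c(tau2 = bt, sigma2 = bs)
}

## Balanced closed-form ML variance components for a single variable.
.balanced_ml_vc <- function(y, g, J, n) {
  gm <- rowsum(y, g)[, 1] / n
  s2 <- sum((y - gm[g])^2) / (J * n - J)
  v <- sum((gm - mean(gm))^2) / J
  c(tau2 = v - s2 / n, sigma2 = s2)
}

#' Monte Carlo oracle for the non-iterative GM/AGM biases
#'
#' Simulates single-variable balanced two-level data, deletes a fixed
#' number of values per group completely at random, imputes once with the
#' non-iterative GM scheme (Bayesian regression on the observed-only
#' group mean) and the non-iterative AGM scheme (observed-only
#' leave-one-out means for observed cases; the observed group mean for
#' missing cases), estimates the variance components by the balanced
#' closed-form ML expressions, and returns the empirical biases with
#' Monte Carlo standard errors.  This is the simulation counterpart of
#' [gm_asymptotic_bias()] and [agm_asymptotic_bias()].
#'
#' @param tau2,sigma2 True variance components.
#' @param n Group size; `n * p` must be a whole number.
#' @param p Proportion missing per group.
#' @param J Number of groups per replication (large, e.g. 1e4).
#' @param reps Number of replications.
#' @param seed Optional integer seed.
#' @return List with matrices `gm` and `agm` (rows: bias, mcse; columns:
#'   tau2, sigma2) and the settings used.
#' @examples
#' noniterative_bias(0.2, 0.8, n = 4, p = 0.25, J = 500, reps = 5, seed = 1)
#' @export
noniterative_bias <- function(tau2, sigma2, n, p, J = 10000, reps = 50,
                              seed = NULL) {
  stopifnot(tau2 >= 0, sigma2 > 0, n >= 2, p > 0, p < 1)
  n_mis <- n * p
  if (abs(n_mis - round(n_mis)) > 1e-8) {
    stop("n * p must be an integer (fixed per-group missing count)")
  }
  n_mis <- as.integer(round(n_mis))
  n_obs <- n - n_mis
  if (n_obs < 2) stop("need at least 2 observed values per group")
  one_rep <- function() {
    g <- rep.int(seq_len(J), rep(n, J))
    y <- rep(rnorm(J, 0, sqrt(tau2)), each = n) +
      rnorm(J * n, 0, sqrt(sigma2))
    ## MCAR with a fixed count: by exchangeability within groups, mask the
    ## first n_mis positions of each group
    pos <- rep.int(seq_len(n), J)
    mis <- which(pos <= n_mis)
    obs <- which(pos > n_mis)
    ym <- y
    ym[mis] <- 0
    gsum <- rowsum(ym, g)[, 1]
    gmo <- gsum / n_obs                          # observed-only group mean
    ## GM: everyone predicted from the observed group mean
    Xg <- cbind(1, gmo[g])
    yg <- y
    yg[mis] <- norm_draw(y, Xg, obs, mis)$values
    ## AGM: observed rows use the leave-one-out observed mean, missing
    ## rows fall back to the observed group mean
    agm <- gmo[g]
    agm[obs] <- (gsum[g[obs]] - y[obs]) / (n_obs - 1)
    Xa <- cbind(1, agm)
    ya <- y
    ya[mis] <- norm_draw(y, Xa, obs, mis)$values
    c(.balanced_ml_vc(yg, g, J, n), .balanced_ml_vc(ya, g, J, n))
  }
  with_seed(seed, {
    out <- t(replicate(reps, one_rep()))
  })
  truth <- c(tau2, sigma2, tau2, sigma2)
  bias <- colMeans(out) - truth
  mcse <- apply(out, 2, sd) / sqrt(reps)
  list(gm = rbind(bias = bias[1:2], mcse = mcse[1:2]),
       agm = rbind(bias = bias[3:4], mcse = mcse[3:4]),
       tau2 = tau2, sigma2 = sigma2, n = n, p = p, J = J, reps = reps)
}

#' Plot asymptotic GM/AGM bias against group size
#'
#' Draws the closed-form asymptotic bias of the between- and
#' within-group variance estimates as a function of group size, one line
#' per missing-data proportion, for both the GM and AGM schemes.
#'
#' @param tau2,sigma2 True variance components.
#' @param n Group sizes to evaluate.
#' @param p Missing-data proportions (lines).
#' @export
plot_asymptotic_bias <- function(tau2 = 0.2, sigma2 = 0.8,
                                 n = seq(4, 40, by = 2),
                                 p = c(0.125, 0.25, 0.5)) {
  op <- par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(par(op))
  for (what in c("tau2", "sigma2")) {
    gm <- sapply(p, function(pp) {
      sapply(n, function(nn) {
        gm_asymptotic_bias(pp, nn, nn * (1 - pp), sigma2)[[what]]
      })
    })
    agm <- sapply(p, function(pp) {
      sapply(n, function(nn) {
        no <- nn * (1 - pp)
        if (no < 2) NA else {
          agm_asymptotic_bias(pp, nn, no, nn - no, tau2, sigma2)[[what]]
        }
      })
    })
    matplot(n, gm, type = "l", lty = 1, col = seq_along(p),
            ylim = range(c(gm, agm), na.rm = TRUE),
            xlab = "group size n",
            ylab = sprintf("asymptotic bias of %s",
                           if (what == "tau2") "between variance"
                           else "within variance"))
    matplot(n, agm, type = "l", lty = 2, col = seq_along(p), add = TRUE)
    abline(h = 0, col = "grey")
    legend("topright", bty = "n", cex = 0.8,
           legend = c(paste0("GM, p=", p), paste0("AGM, p=", p)),
           lty = rep(1:2, each = length(p)),
           col = rep(seq_along(p), 2))
  }
  invisible(NULL)
}
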