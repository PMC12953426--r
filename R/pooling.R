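## Rubin's rules for combining per-imputation estimates.

#' Pool estimates across imputations by Rubin's rules
#'
#' Combines `m` point estimates and their squared standard errors into a
#' pooled estimate `Qbar`, within-imputation variance `W`, between-
#' imputation variance `B`, total variance `T = W + (1 + 1/m) B`, the
#' classic Rubin degrees of freedom, and a t-based confidence interval.
#' When the estimates are identical across imputations (`B = 0`) the
#' degrees of freedom are infinite and the interval uses `W` alone.
#'
#' @param estimates Numeric vector of per-imputation point estimates
#'   (`m >= 2`).
#' @param variances Matching squared standard errors.
#' @param level Confidence level for the interval.
#' @param df_adjust If `TRUE`, apply the Barnard–Rubin small-sample
#'   degrees-of-freedom adjustment using `n_com` complete-data degrees of
#'   freedom; off by default.
#' @param n_com Complete-data degrees of freedom, required when
#'   `df_adjust = TRUE`.
#' @return An object of class `mi_pooled` with fields `qbar`, `W`, `B`,
#'   `T`, `df`, `ci`, `level`, `m`.
#' @examples
#' pool_rubin(c(0.4, 0.6), c(0.01, 0.01))
#' @export
pool_rubin <- function(estimates, variances, level = 0.95,
                       df_adjust = FALSE, n_com = NULL) {
  m <- length(estimates)
  if (m < 2) stop("pooling requires m >= 2 imputations")
  stopifnot(length(variances) == m, all(variances >= 0), level > 0, level < 1)
  qbar <- mean(estimates)
  W <- mean(variances)
  B <- var(estimates)
  Tv <- W + (1 + 1 / m) * B
  if (B <= 0) {
    df <- Inf
    Tv <- W
    half <- qnorm(1 - (1 - level) / 2) * sqrt(W)
  } else {
    df <- (m - 1) * (1 + W / ((1 + 1 / m) * B))^2
    if (df_adjust) {
      if (is.null(n_com)) stop("n_com is required for the adjusted df")
      lam <- (1 + 1 / m) * B / Tv
      df_obs <- (n_com + 1) / (n_com + 3) * n_com * (1 - lam)
      df <- 1 / (1 / df + 1 / df_obs)
    }
    half <- qt(1 - (1 - level) / 2, df) * sqrt(Tv)
  }
  structure(list(qbar = qbar, W = W, B = B, T = Tv, df = df,
                 ci = c(qbar - half, qbar + half), level = level, m = m),
            class = "mi_pooled")
}

#' @export
print.mi_pooled <- function(x, ...) {
  cat(sprintf("Pooled estimate (m = %d): %.4f\n", x$m, x$qbar))
  cat(sprintf("  W = %.5f, B = %.5f, T = %.5f, df = %.2f\n",
              x$W, x$B, x$T, x$df))
  cat(sprintf("  %d%% CI: [%.4f, %.4f]\n", round(100 * x$level),
              x$ci[1], x$ci[2]))
  invisible(x)
}
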