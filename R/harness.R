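## Simulation harness: generate -> ampute -> impute -> analyze -> pool
## over replications, with bias / coverage / Monte Carlo standard errors.
##
## Within a replication all methods share the same generated and amputed
## dataset (a paired design), so method contrasts are less noisy than
## the marginal Monte Carlo SEs suggest.  A replication that fails for
## one method is dropped only for that method and counted.

.mi_methods <- c("gm", "agm", "gm_star", "agm_star", "twolevel")

#' Define a simulation study condition
#'
#' @param population A [two_level_population()].
#' @param design A [group_size_design()].
#' @param missing A [missingness_spec()].
#' @param methods Subset of `c("CD", "LD", "gm", "agm", "gm_star",
#'   "agm_star", "twolevel")`; `"CD"` analyzes the complete data, `"LD"`
#'   the listwise-deleted data, the rest are imputation methods.
#' @param analyses List of analyses; each element is a list with fields
#'   `model` (`"empty"`, `"latent"`, `"manifest"`, `"single"` or
#'   `"single_multi"`), `outcome`, `predictor` (unused for `"empty"`;
#'   ignored for `"single_multi"`, which uses all other variables and
#'   reports the coefficient named in `parameter`), `parameter` (e.g.
#'   `"icc"`, `"beta_b"`, `"gamma_b"`, or a coefficient name for the
#'   single-level models) and `truth` (a number, or `"cd"` to use the
#'   mean complete-data estimate as the reference value).
#' @param replications Number of Monte Carlo replications.
#' @param seed Master seed; every replication and stage derives its own
#'   substream from it.
#' @param m,iterations Imputation settings passed to [fcs_impute()].
#' @param level Nominal confidence level for coverage.
#' @param size_transform Group-size transform for the starred methods.
#' @return An object of class `study_config`.
#' @export
study_config <- function(population, design, missing, methods, analyses,
                         replications, seed, m = 10, iterations = 10,
                         level = 0.95, size_transform = function(n) 1 / n) {
  stopifnot(inherits(population, "two_level_population"),
            inherits(design, "group_size_design"),
            inherits(missing, "missingness_spec"),
            replications >= 1, m >= 1, iterations >= 1)
  methods <- match.arg(methods, c("CD", "LD", .mi_methods),
                       several.ok = TRUE)
  for (an in analyses) {
    stopifnot(an$model %in% c("empty", "latent", "manifest", "single",
                              "single_multi"),
              !is.null(an$parameter), !is.null(an$truth))
    if (identical(an$truth, "cd") && !("CD" %in% methods)) {
      stop("truth = 'cd' requires the CD method in the condition")
    }
  }
  structure(list(population = population, design = design,
                 missing = missing, methods = methods, analyses = analyses,
                 replications = as.integer(replications), seed = seed,
                 m = m, iterations = iterations, level = level,
                 size_transform = size_transform),
            class = "study_config")
}

## Point estimate and squared SE (plus CI df) for one analysis on one
## completed dataset.
.analysis_fit <- function(dat, an, group = "group") {
  if (an$model == "empty") {
    f <- fit_empty(dat, an$outcome, group)
    par <- an$parameter
    c(f$estimates[[par]], f$std_errors[[par]]^2, Inf)
  } else if (an$model == "latent") {
    f <- fit_latent_covariate(dat, an$predictor, an$outcome, group)
    par <- an$parameter
    est <- f$estimates[[par]]
    if (is.na(est)) stop("between-group variance at boundary; slope undefined")
    c(est, f$std_errors[[par]]^2, Inf)
  } else if (an$model == "manifest") {
    f <- fit_manifest_covariate(dat, an$predictor, an$outcome, group)
    par <- an$parameter
    c(f$estimates[[par]], f$std_errors[[par]]^2, Inf)
  } else {
    preds <- if (an$model == "single_multi") {
      setdiff(.value_cols(dat, group), an$outcome)
    } else {
      an$predictor
    }
    f <- fit_single_level(dat, an$outcome, preds, group)
    par <- an$parameter
    c(f$estimates[[par]], f$std_errors[[par]]^2, f$extra$df)
  }
}

#' Run one simulation condition
#'
#' Executes `replications` independent replications of the full pipeline
#' and summarizes bias, coverage of nominal confidence intervals, and
#' their Monte Carlo standard errors (`SD/sqrt(R)` for bias,
#' `sqrt(c(1-c)/R)` for coverage) per method and parameter.
#'
#' @param config A [study_config()].
#' @param progress Print a dot every 25 replications.
#' @return A `condition_result` data frame with columns `method`,
#'   `model`, `parameter`, `truth`, `bias`, `mcse_bias`, `coverage`,
#'   `mcse_coverage`, `n_used`, `n_fail`.  Per-replication estimates are
#'   attached as attribute `"estimates"`.
#' @export
run_condition <- function(config, progress = FALSE) {
  stopifnot(inherits(config, "study_config"))
  R <- config$replications
  methods <- config$methods
  analyses <- config$analyses
  nA <- length(analyses)
  alab <- vapply(analyses, function(a) paste(a$model, a$parameter, sep = "."),
                 character(1))
  est <- array(NA_real_, c(R, length(methods), nA),
               dimnames = list(NULL, methods, alab))
  lo <- est
  hi <- est
  fail <- matrix(FALSE, R, length(methods), dimnames = list(NULL, methods))
  failmsg <- character(0)
  alpha <- 1 - config$level
  sizes <- draw_group_sizes(config$design)
  for (r in seq_len(R)) {
    rseed <- substream_seed(config$seed, r)
    dat <- simulate_complete(config$population, sizes,
                             seed = substream_seed(rseed, 1))
    amp <- ampute(dat, config$missing, seed = substream_seed(rseed, 2))
    for (mi in seq_along(methods)) {
      meth <- methods[mi]
      res <- tryCatch({
        if (meth == "CD") {
          stack <- list(dat)
        } else if (meth == "LD") {
          stack <- list(listwise_delete(amp))
        } else {
          imp <- fcs_impute(amp, meth, m = config$m,
                            iterations = config$iterations,
                            seed = substream_seed(rseed, 10 + mi),
                            size_transform = config$size_transform)
          stack <- imp$imputations
        }
        out <- matrix(NA_real_, nA, 3)
        for (a in seq_len(nA)) {
          fits <- vapply(stack, .analysis_fit, numeric(3), an = analyses[[a]])
          if (length(stack) == 1) {
            e <- fits[1, 1]
            se <- sqrt(fits[2, 1])
            df <- fits[3, 1]
            qq <- if (is.finite(df)) qt(1 - alpha / 2, df) else
              qnorm(1 - alpha / 2)
            out[a, ] <- c(e, e - qq * se, e + qq * se)
          } else {
            pl <- pool_rubin(fits[1, ], fits[2, ], level = config$level)
            out[a, ] <- c(pl$qbar, pl$ci)
          }
        }
        out
      }, error = function(e) e)
      if (inherits(res, "error")) {
        fail[r, mi] <- TRUE
        failmsg <- c(failmsg,
                     sprintf("rep %d, %s: %s", r, meth, conditionMessage(res)))
      } else {
        est[r, mi, ] <- res[, 1]
        lo[r, mi, ] <- res[, 2]
        hi[r, mi, ] <- res[, 3]
      }
    }
    if (progress && r %% 25 == 0) cat(".")
  }
  if (progress) cat("\n")
  ## resolve truths (CD-referenced parameters use the mean CD estimate)
  truth <- numeric(nA)
  for (a in seq_len(nA)) {
    tv <- analyses[[a]]$truth
    truth[a] <- if (identical(tv, "cd")) {
      mean(est[!fail[, "CD"], "CD", a])
    } else {
      as.numeric(tv)
    }
  }
  rows <- list()
  for (mi in seq_along(methods)) {
    ok <- !fail[, mi]
    for (a in seq_len(nA)) {
      e <- est[ok, mi, a]
      cov <- mean(lo[ok, mi, a] <= truth[a] & truth[a] <= hi[ok, mi, a])
      rows[[length(rows) + 1]] <- data.frame(
        method = methods[mi],
        model = analyses[[a]]$model,
        parameter = analyses[[a]]$parameter,
        truth = truth[a],
        bias = mean(e) - truth[a],
        mcse_bias = sd(e) / sqrt(length(e)),
        coverage = cov,
        mcse_coverage = sqrt(cov * (1 - cov) / length(e)),
        n_used = length(e),
        n_fail = sum(!ok))
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("condition_result", "data.frame")
  attr(out, "estimates") <- est
  attr(out, "ci_low") <- lo
  attr(out, "ci_high") <- hi
  attr(out, "failures") <- failmsg
  attr(out, "config") <- config
  out
}

#' @export
print.condition_result <- function(x, ...) {
  cat(sprintf("Simulation condition: %d replication(s)\n",
              attr(x, "config")$replications))
  df <- as.data.frame(x)
  df$bias <- round(df$bias, 4)
  df$mcse_bias <- round(df$mcse_bias, 4)
  df$coverage <- round(df$coverage, 3)
  df$mcse_coverage <- round(df$mcse_coverage, 3)
  df$truth <- round(df$truth, 4)
  print(df, row.names = FALSE)
  nf <- length(attr(x, "failures"))
  if (nf) cat(sprintf("%d method-replication failure(s) excluded\n", nf))
  invisible(x)
}

#' Write simulation results to disk
#'
#' Writes a long-format CSV (one row per condition, method and
#' parameter) and a human-readable text table.
#'
#' @param results A `condition_result` or a named list of them (names
#'   become the `condition` column).
#' @param path Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(results, path) {
  if (inherits(results, "condition_result")) {
    results <- list(condition = results)
  }
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  long <- do.call(rbind, lapply(names(results), function(nm) {
    df <- as.data.frame(results[[nm]])
    if (nrow(df)) cbind(condition = nm, df) else
      cbind(condition = character(0), df)
  }))
  if (is.null(long)) {
    long <- data.frame(condition = character(0), method = character(0),
                       model = character(0), parameter = character(0),
                       truth = numeric(0), bias = numeric(0),
                       mcse_bias = numeric(0), coverage = numeric(0),
                       mcse_coverage = numeric(0), n_used = integer(0),
                       n_fail = integer(0))
  }
  csv <- file.path(path, "results.csv")
  write.csv(long, csv, row.names = FALSE)
  txt <- file.path(path, "results.txt")
  con <- file(txt, "w")
  for (nm in names(results)) {
    writeLines(sprintf("== %s ==", nm), con)
    writeLines(capture_table(results[[nm]]), con)
    writeLines("", con)
  }
  close(con)
  invisible(c(csv, txt))
}

capture_table <- function(x) {
  utils::capture.output(print(x))
}
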