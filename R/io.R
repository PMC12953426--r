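## File interfaces: long-format clustered CSV (empty cell = missing) and
## study configurations from YAML or JSON.

#' Read clustered data from CSV
#'
#' Long format: a `group` column plus numeric variable columns; empty
#' cells are missing values.
#'
#' @param path CSV file path.
#' @param group Name of the group identifier column.
#' @return A data frame with `NA` at missing cells.
#' @export
read_clustered_csv <- function(path, group = "group") {
  d <- read.csv(path, na.strings = c("", "NA"), check.names = FALSE)
  if (!group %in% names(d)) {
    stop(sprintf("no '%s' column in %s", group, path))
  }
  d
}

#' Write clustered data to CSV
#'
#' Missing cells are written as empty fields, so the missingness mask
#' round-trips losslessly through [read_clustered_csv()].
#'
#' @param data Clustered data frame.
#' @param path Output file path.
#' @export
write_clustered_csv <- function(data, path) {
  write.csv(data, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Write an imputed stack to a directory
#'
#' Each completed copy goes to `imp_001.csv`, ... together with a JSON
#' manifest recording the method, seed, iteration count and any dropped
#' predictor columns.
#'
#' @param x A `gm_mids` object from [fcs_impute()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the manifest path.
#' @export
write_imputed_stack <- function(x, dir) {
  stopifnot(inherits(x, "gm_mids"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_len(x$m)) {
    write_clustered_csv(x$imputations[[i]],
                        file.path(dir, sprintf("imp_%03d.csv", i)))
  }
  manifest <- list(method = x$method, m = x$m, iterations = x$iterations,
                   seed = x$seed, imputed_variables = x$incomplete,
                   dropped_columns = x$dropped)
  mp <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, null = "null")
  invisible(mp)
}

#' Read a study configuration from YAML or JSON
#'
#' Expected keys: `population: {iccs, rho_b, rho_w}`, `design: {J, n,
#' shape, interval}`, `missing: {targets, p, lambda, predictor}`,
#' `methods`, `analyses` (list with `model`, `outcome`, `predictor`,
#' `parameter`, `truth`), `replications`, `m`, `iterations`, `seed`.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A [study_config()].
#' @export
read_study_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  }
  ## YAML 1.1 reads a bare key `n` as the boolean FALSE; map it back
  if (!is.null(cfg$design) && is.null(cfg$design$n) &&
      !is.null(cfg$design[["FALSE"]])) {
    cfg$design$n <- cfg$design[["FALSE"]]
  }
  pop <- make_population(as.numeric(cfg$population$iccs),
                         rho_b = cfg$population$rho_b %||% 0,
                         rho_w = cfg$population$rho_w %||% 0)
  des <- group_size_design(cfg$design$J, cfg$design$n,
                           shape = cfg$design$shape %||% "balanced",
                           interval = cfg$design$interval %||% 0)
  mis <- missingness_spec(cfg$missing$targets, cfg$missing$p,
                          lambda = cfg$missing$lambda %||% 0,
                          predictor = cfg$missing$predictor)
  study_config(pop, des, mis,
               methods = cfg$methods,
               analyses = cfg$analyses,
               replications = cfg$replications,
               seed = cfg$seed,
               m = cfg$m %||% 10,
               iterations = cfg$iterations %||% 10,
               level = cfg$level %||% 0.95)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
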