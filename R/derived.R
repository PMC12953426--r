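## Deterministic derived covariates used by the imputation models: group
## means, adjusted (leave-one-out) group means, within-group centering,
## and group-size terms.  All are pure functions of (values, group).

.group_index <- function(group) {
  f <- factor(group, levels = unique(group))
  g <- as.integer(f)
  list(g = g, sizes = tabulate(g, nbins = nlevels(f)))
}

#' Per-row group means
#'
#' @param values Numeric vector, fully observed.
#' @param group Group identifier per row.
#' @return Numeric vector carrying each row's group mean.
#' @examples
#' group_means(c(1, 3, 5), c("a", "a", "b"))
#' @export
group_means <- function(values, group) {
  if (anyNA(values)) stop("group_means operates on completed data")
  gi <- .group_index(group)
  m <- rowsum(values, gi$g)[, 1] / gi$sizes
  unname(m[gi$g])
}

#' Per-row adjusted (leave-one-out) group means
#'
#' Row i in group j receives the mean of the other `n_j - 1` values, so
#' the target's own value never enters its predictor.  The algebraic
#' identity `n_j * gm = (n_j - 1) * agm_i + y_i` holds exactly for every
#' row.
#'
#' @inheritParams group_means
#' @return Numeric vector of adjusted group means.
#' @examples
#' adjusted_group_means(c(1, 2, 3), c(1, 1, 1))
#' @export
adjusted_group_means <- function(values, group) {
  if (anyNA(values)) stop("adjusted_group_means operates on completed data")
  gi <- .group_index(group)
  if (any(gi$sizes < 2)) {
    stop("adjusted group means are undefined for groups of size 1")
  }
  s <- rowsum(values, gi$g)[, 1]
  unname((s[gi$g] - values) / (gi$sizes[gi$g] - 1))
}

#' Within-group centered values
#'
#' @inheritParams group_means
#' @return `values` minus the row's group mean; sums to zero within each
#'   group.
#' @export
within_center <- function(values, group) {
  values - group_means(values, group)
}

#' Per-row group-size terms
#'
#' Computes `w_j = f(n_j)` for every row; the default transform is the
#' reciprocal group size.  Interactions with group-mean terms are formed
#' by elementwise multiplication of the returned vector with the term.
#'
#' @param group Group identifier per row.
#' @param f Size transform; must return a finite value for every realized
#'   group size.
#' @return Numeric vector, constant within each group.
#' @examples
#' size_terms(rep(1:2, c(4, 2)))
#' @export
size_terms <- function(group, f = function(n) 1 / n) {
  gi <- .group_index(group)
  w <- f(gi$sizes)
  if (any(!is.finite(w))) {
    stop("size transform is undefined for some realized group size")
  }
  unname(w[gi$g])
}
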