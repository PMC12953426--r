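## Deterministic seed substreams.
##
## A master seed spawns per-replication, per-stage sub-seeds through an
## integer hash so that individual replications (and individual chains
## within an imputation run) are reproducible in isolation and
## order-independent.  All arithmetic stays below 2^53, so it is exact in
## doubles, and the result is a valid 32-bit seed.

#' Derive a reproducible sub-seed from a master seed
#'
#' Folds an arbitrary sequence of integer indices (replication number,
#' stage number, chain number, ...) into a master seed using a
#' multiplicative-congruential hash.  The same `(master, ...)` always maps
#' to the same sub-seed, and different index paths map to effectively
#' independent streams.
#'
#' @param master Integer master seed.
#' @param ... Integer indices identifying the substream.
#' @return A single integer seed in `[1, 2147483646]`.
#' @examples
#' substream_seed(1, 5, 2)
#' @export
substream_seed <- function(master, ...) {
  idx <- c(...)
  h <- (as.double(master) %% 2147483647 + 2147483647) %% 2147483647
  for (k in idx) {
    h <- (h * 48271 + (as.double(k) %% 2147483647) + 1) %% 2147483647
  }
  ## one extra scramble so master and master+1 do not give adjacent streams
  h <- (h * 69621 + 1) %% 2147483647
  as.integer(h %% 2147483646) + 1L
}

## Run expr after seeding the RNG (no-op when seed is NULL).
with_seed <- function(seed, expr) {
  if (!is.null(seed)) set.seed(seed)
  expr
}
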