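# Internal helpers shared across modules.

#' Derive a reproducible substream seed
#'
#' Folds a master seed and any number of integer indices into a single seed
#' in `[1, 2^31 - 2]`.  Used so that per-subject, per-replicate and per-cell
#' random streams are reproducible regardless of execution order or worker
#' count.  All arithmetic stays below 2^53 so the fold is exact in doubles.
#'
#' @param seed master seed (single integer-valued number).
#' @param ... further integer-valued indices (subject, replicate, cell, ...).
#' @return a single integer seed.
#' @export
derive_seed <- function(seed, ...) {
  idx <- c(...)
  s <- (abs(seed) %% 2147483647)
  for (v in c(1L, idx)) {
    s <- (s * 69069 + abs(v) + 1) %% 2147483647
  }
  as.integer(s %% 2147483646 + 1)
}

# Composite Simpson quadrature of f on [a, b] with an odd number of nodes.
simpson <- function(f, a, b, n_nodes = 2001L) {
  if (n_nodes %% 2L == 0L) n_nodes <- n_nodes + 1L
  x <- seq(a, b, length.out = n_nodes)
  w <- rep(c(2, 4), length.out = n_nodes)
  w[1] <- 1
  w[n_nodes] <- 1
  h <- (b - a) / (n_nodes - 1)
  sum(w * f(x)) * h / 3
}

`%||%` <- function(x, y) if (is.null(x)) y else x

stop_covgof <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "covgof_error")))
}
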