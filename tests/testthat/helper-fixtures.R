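# Shared fixtures built in code at test time.

# A small irregular sample with interleaved subjects, duplicate times and
# unsorted within-subject order.
tiny_irregular_sample <- function() {
  fd_sample(
    subject = c("b", "a", "b", "a", "b", "c"),
    time = c(0.5, -0.2, 0.5, 0.9, -0.7, 0.1),
    value = c(1.1, -0.4, 0.3, 2.2, 0.0, -1.5),
    domain = c(-1, 1)
  )
}

# Centred sample drawn from the quadratic-polynomial null; returned as an
# fd_sample (treated as already de-meaned by fit_null etc.).
null_model_sample <- function(n, m, seed, sigma2 = 1,
                              V0 = matrix(c(1, -0.5, -0.5, 1), 2)) {
  ds <- sim_design(n = n, m = m, seed = seed, noise_sd = sqrt(sigma2),
                   re_cov = V0)
  simulate_dataset(ds)
}

# Independent dense evaluation of the null marginal log-likelihood
# (per-subject Cholesky of V_i), used as an oracle against the package's
# Woodbury path.
naive_null_loglik <- function(demeaned, fit) {
  ids <- demeaned$data$subject
  tot <- 0
  for (id in unique(ids)) {
    rows <- which(ids == id)
    t_i <- demeaned$data$time[rows]
    y_i <- demeaned$data$value[rows]
    G <- outer(t_i, t_i, function(a, b) eval_null_cov(fit, a, b))
    Vi <- G + diag(fit$sigma2, length(t_i))
    ch <- chol(Vi)
    tot <- tot - 0.5 * (2 * sum(log(diag(ch))) +
                          sum(backsolve(ch, y_i, transpose = TRUE)^2))
  }
  tot
}

# Brute-force symmetric tensor-product least squares: materializes the
# ordered-pair design over the free upper-triangle coefficients and solves
# the normal equations directly.
brute_force_smoother <- function(demeaned, basis) {
  ids <- demeaned$data$subject
  H <- basis$H
  rows <- list()
  resp <- numeric(0)
  for (id in unique(ids)) {
    sel <- which(ids == id)
    B <- eval_basis(basis, demeaned$data$time[sel])
    y <- demeaned$data$value[sel]
    m <- length(sel)
    for (j in seq_len(m)) for (jp in seq_len(m)) {
      if (j == jp) next
      rows[[length(rows) + 1]] <- as.vector(outer(B[j, ], B[jp, ]))
      resp <- c(resp, y[j] * y[jp])
    }
  }
  X <- do.call(rbind, rows)
  # map to symmetric free parameters theta_{h<=l}
  p <- H * (H + 1) / 2
  Tm <- matrix(0, H * H, p)
  k <- 0
  for (l in seq_len(H)) for (h in seq_len(l)) {
    k <- k + 1
    Tm[(l - 1) * H + h, k] <- 1
    Tm[(h - 1) * H + l, k] <- 1
  }
  Xs <- X %*% Tm
  theta_free <- solve(crossprod(Xs), crossprod(Xs, resp))
  Theta <- matrix(0, H, H)
  k <- 0
  for (l in seq_len(H)) for (h in seq_len(l)) {
    k <- k + 1
    Theta[h, l] <- theta_free[k]
    Theta[l, h] <- theta_free[k]
  }
  Theta
}
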