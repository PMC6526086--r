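#' Parametric null covariance models
#'
#' The primary null family is the quadratic polynomial covariance
#' \deqn{G_0(t,t') = \sigma_0^2 + \sigma_{01}(t + t') + \sigma_1^2 t t',}
#' induced by the linear random-effects model \eqn{X_i(t) = b_{0i} +
#' b_{1i} t} with \eqn{(b_{0i}, b_{1i})^\top \sim N(0, V_0)}.  A stationary
#' squared-exponential family \eqn{G_0(t,t') = \theta e^{-(t-t')^2 /
#' \delta^2}} is also available to illustrate that any smooth parametric
#' null can be plugged in.
#'
#' `null_cov_fit()` constructs a fit object from known parameters (useful
#' for simulation and testing); [fit_null()] estimates the parameters by
#' maximum likelihood.
#'
#' @param family `"quadratic_polynomial"` or `"squared_exponential"`.
#' @param V0 symmetric positive semidefinite 2x2 random-effects covariance
#'   (quadratic family).
#' @param sigma2 noise variance \eqn{\sigma^2 \ge 0}.
#' @param theta,delta squared-exponential parameters (\eqn{\theta \ge 0},
#'   \eqn{\delta > 0}).
#' @param loglik,converged optional fit metadata.
#' @return an object of class `null_cov_fit`.
#' @export
null_cov_fit <- function(family = c("quadratic_polynomial",
                                    "squared_exponential"),
                         V0 = NULL, sigma2 = 0, theta = NULL, delta = NULL,
                         loglik = NA_real_, converged = NA) {
  family <- match.arg(family)
  if (sigma2 < 0) stop_covgof("sigma2 must be >= 0", "covgof_param_error")
  if (family == "quadratic_polynomial") {
    stopifnot(is.matrix(V0), all(dim(V0) == 2))
    V0 <- (V0 + t(V0)) / 2
    if (min(eigen(V0, symmetric = TRUE, only.values = TRUE)$values) < -1e-8) {
      stop_covgof("V0 must be positive semidefinite", "covgof_param_error")
    }
  } else {
    stopifnot(is.numeric(theta), is.numeric(delta))
    if (theta < 0 || delta <= 0) {
      stop_covgof("need theta >= 0 and delta > 0", "covgof_param_error")
    }
  }
  out <- list(family = family, V0 = V0, theta = theta, delta = delta,
              sigma2 = sigma2, loglik = loglik, converged = converged)
  class(out) <- "null_cov_fit"
  out
}

#' @export
print.null_cov_fit <- function(x, ...) {
  if (x$family == "quadratic_polynomial") {
    cat(sprintf(
      "<null_cov_fit> quadratic polynomial: s0^2=%.4g, s01=%.4g, s1^2=%.4g, sigma2=%.4g\n",
      x$V0[1, 1], x$V0[1, 2], x$V0[2, 2], x$sigma2))
  } else {
    cat(sprintf(
      "<null_cov_fit> squared exponential: theta=%.4g, delta=%.4g, sigma2=%.4g\n",
      x$theta, x$delta, x$sigma2))
  }
  if (is.finite(x$loglik)) {
    cat(sprintf("  loglik=%.4f, converged=%s\n", x$loglik, x$converged))
  }
  invisible(x)
}

#' Evaluate a null covariance function
#'
#' Returns \eqn{G_0(t, t')} for the fitted (or user-specified) family.
#' Arguments are recycled elementwise; the surface is symmetric in its two
#' time arguments.  The noise variance is not included.
#'
#' @param fit a `null_cov_fit`.
#' @param t,t2 numeric vectors of times.
#' @return numeric vector of covariances.
#' @examples
#' f <- null_cov_fit(V0 = matrix(c(1, -0.5, -0.5, 1), 2), sigma2 = 1)
#' eval_null_cov(f, 1, 1)  # 1 - 0.5 * 2 + 1 = 1
#' @export
eval_null_cov <- function(fit, t, t2) {
  stopifnot(inherits(fit, "null_cov_fit"))
  if (fit$family == "quadratic_polynomial") {
    fit$V0[1, 1] + fit$V0[1, 2] * (t + t2) + fit$V0[2, 2] * t * t2
  } else {
    fit$theta * exp(-(t - t2)^2 / fit$delta^2)
  }
}

#' Fit a parametric null covariance by maximum likelihood
#'
#' Maximizes the marginal log-likelihood of the de-meaned data,
#' \deqn{\ell = \sum_i -\tfrac12\left(\log|V_i| +
#'   \tilde Y_i^\top V_i^{-1} \tilde Y_i\right), \qquad
#'   V_i = G_0(t_i, t_i) + \sigma^2 I_{m_i},}
#' over the family parameters and \eqn{\sigma^2} (the additive
#' \eqn{-\tfrac{N}{2}\log 2\pi} constant is omitted from the reported
#' log-likelihood).  Because the data are de-meaned beforehand, no fixed
#' effects enter the fit.  For the quadratic family the covariance is
#' parameterized through the log-Cholesky factor of \eqn{V_0} and
#' \eqn{\log\sigma^2}, so \eqn{V_0} stays positive semidefinite and
#' \eqn{\sigma^2 > 0} throughout; the likelihood is evaluated through the
#' low-rank Woodbury identity, vectorized across subjects, so the cost per
#' objective evaluation is O(n).  Optimization uses `nlminb` from two
#' starts (a pooled-variance start and a per-subject least-squares moment
#' start); the better optimum is kept.
#'
#' @param demeaned an `fd_demeaned` (see [demean()]); a plain [fd_sample]
#'   is accepted and treated as already centred.
#' @param family the null family to fit.
#' @param control optional list: `rel.tol` (default `1e-10`), `iter.max`
#'   (default 500).
#' @return a `null_cov_fit` with `loglik` and `converged` filled in.
#' @export
fit_null <- function(demeaned,
                     family = c("quadratic_polynomial",
                                "squared_exponential"),
                     control = list()) {
  stopifnot(inherits(demeaned, "fd_sample"))
  family <- match.arg(family)
  ctrl <- list(rel.tol = control$rel.tol %||% 1e-10,
               iter.max = control$iter.max %||% 500L)
  dat <- fd_split(demeaned)
  mi <- vapply(dat, function(s) length(s$times), 1L)
  if (all(mi == 1L)) {
    stop_covgof(
      "all subjects have a single observation; intercept variance and noise variance are confounded",
      "covgof_identifiability_error")
  }
  if (family == "quadratic_polynomial") {
    fit_null_quadratic(dat, ctrl)
  } else {
    fit_null_sqexp(dat, ctrl)
  }
}

#' Simulate one subject trajectory from a fitted null model
#'
#' For the quadratic family, draws \eqn{(b_0, b_1)^\top \sim N(0, \hat
#' V_0)} and returns the exactly linear trajectory \eqn{b_0 + b_1 t}.  For
#' a generic family, returns \eqn{\hat V_0^{1/2} z} through the symmetric
#' square root of the null covariance matrix at `times`.  Measurement
#' noise is not added; callers add \eqn{N(0, \hat\sigma^2)} residuals.
#'
#' @param fit a `null_cov_fit`.
#' @param times numeric vector of observation times.
#' @param seed optional seed for the draw.
#' @return numeric vector of the same length as `times`.
#' @export
simulate_null_subject <- function(fit, times, seed = NULL) {
  stopifnot(inherits(fit, "null_cov_fit"))
  if (!is.null(seed)) set.seed(seed)
  if (fit$family == "quadratic_polynomial") {
    b <- drop(sym_sqrt(fit$V0) %*% stats::rnorm(2))
    b[1] + b[2] * times
  } else {
    G <- outer(times, times, function(a, b) eval_null_cov(fit, a, b))
    drop(sym_sqrt(G) %*% stats::rnorm(length(times)))
  }
}

# Symmetric PSD square root via eigendecomposition (negative eigenvalues,
# which can only arise from roundoff, are clipped at zero).
sym_sqrt <- function(V) {
  ee <- eigen((V + t(V)) / 2, symmetric = TRUE)
  if (min(ee$values) < -1e-8 * max(abs(ee$values), 1)) {
    stop_covgof("covariance matrix is not positive semidefinite",
                "covgof_param_error")
  }
  ee$vectors %*% (sqrt(pmax(ee$values, 0)) * t(ee$vectors))
}

#' Marginal log-likelihood of de-meaned data under a null fit
#'
#' Evaluates \eqn{\sum_i -\frac12 (\log|V_i| + \tilde Y_i^\top V_i^{-1}
#' \tilde Y_i)} at the parameters stored in `fit` (the additive
#' \eqn{2\pi} constant is omitted, matching [fit_null()]).
#'
#' @param demeaned an `fd_demeaned` or centred [fd_sample].
#' @param fit a `null_cov_fit`.
#' @return a single number.
#' @export
null_loglik <- function(demeaned, fit) {
  stopifnot(inherits(demeaned, "fd_sample"), inherits(fit, "null_cov_fit"))
  dat <- fd_split(demeaned)
  if (fit$family == "quadratic_polynomial") {
    st <- lowrank_stats(dat, q = 2)
    -negll_lowrank(fit$V0, fit$sigma2, st)
  } else {
    -negll_dense(dat, fit)
  }
}

# ---- internal: low-rank (random-effects) likelihood --------------------------

# Per-subject sufficient statistics for a random-effects design
# Z_i = [1, t, ..., t^(q-1)]: packed upper triangle of A_i = Z_i'Z_i,
# c_i = Z_i' y_i, d_i = y_i'y_i and m_i.  Everything downstream is
# vectorized across subjects.
lowrank_stats <- function(dat, q) {
  n <- length(dat)
  ut <- upper_tri_index(q)
  Amat <- matrix(0, n, q * (q + 1) / 2)
  Cmat <- matrix(0, n, q)
  dvec <- numeric(n)
  mivec <- integer(n)
  for (i in seq_len(n)) {
    t_i <- dat[[i]]$times
    y_i <- dat[[i]]$values
    Z <- stats::poly(t_i, degree = q - 1, raw = TRUE, simple = TRUE)
    Z <- cbind(1, Z)
    A <- crossprod(Z)
    Amat[i, ] <- A[upper.tri(A, diag = TRUE)]
    Cmat[i, ] <- crossprod(Z, y_i)
    dvec[i] <- sum(y_i^2)
    mivec[i] <- length(t_i)
  }
  list(q = q, Amat = Amat, Cmat = Cmat, dvec = dvec, mivec = mivec,
       Aidx = ut)
}

# Map (j,k) of a symmetric q x q matrix to the packed upper-triangle column.
upper_tri_index <- function(q) {
  idx <- matrix(0L, q, q)
  pos <- 0L
  for (k in seq_len(q)) for (j in seq_len(k)) {
    pos <- pos + 1L
    idx[j, k] <- pos
    idx[k, j] <- pos
  }
  idx
}

# Negative printed log-likelihood for V_i = Z_i V0 Z_i' + s2 I, vectorized
# across subjects via the Woodbury identity
#   V_i^{-1} = I/s2 - Z_i V0 (I + A_i V0 / s2)^{-1} Z_i' / s2^2,
#   log|V_i| = m_i log s2 + log det(I + A_i V0 / s2),
# which never requires inverting V0 (so the boundary of the PSD cone is
# safe).  V0 is q x q with q = 2 or 3.
negll_lowrank <- function(V0, s2, st) {
  q <- st$q
  A <- function(j, k) st$Amat[, st$Aidx[j, k]]
  # M = I + A V0 / s2, entries as length-n vectors
  M <- vector("list", q * q)
  dim(M) <- c(q, q)
  for (j in seq_len(q)) for (k in seq_len(q)) {
    acc <- 0
    for (l in seq_len(q)) acc <- acc + A(j, l) * V0[l, k]
    M[[j, k]] <- (if (j == k) 1 else 0) + acc / s2
  }
  if (q == 2) {
    detM <- M[[1, 1]] * M[[2, 2]] - M[[1, 2]] * M[[2, 1]]
    adj <- vector("list", 4); dim(adj) <- c(2, 2)
    adj[[1, 1]] <- M[[2, 2]]; adj[[1, 2]] <- -M[[1, 2]]
    adj[[2, 1]] <- -M[[2, 1]]; adj[[2, 2]] <- M[[1, 1]]
  } else if (q == 3) {
    co <- function(a, b, c, d) M[[a[1], a[2]]] * M[[b[1], b[2]]] -
      M[[c[1], c[2]]] * M[[d[1], d[2]]]
    detM <- M[[1, 1]] * (M[[2, 2]] * M[[3, 3]] - M[[2, 3]] * M[[3, 2]]) -
      M[[1, 2]] * (M[[2, 1]] * M[[3, 3]] - M[[2, 3]] * M[[3, 1]]) +
      M[[1, 3]] * (M[[2, 1]] * M[[3, 2]] - M[[2, 2]] * M[[3, 1]])
    adj <- vector("list", 9); dim(adj) <- c(3, 3)
    adj[[1, 1]] <- co(c(2, 2), c(3, 3), c(2, 3), c(3, 2))
    adj[[1, 2]] <- -co(c(1, 2), c(3, 3), c(1, 3), c(3, 2))
    adj[[1, 3]] <- co(c(1, 2), c(2, 3), c(1, 3), c(2, 2))
    adj[[2, 1]] <- -co(c(2, 1), c(3, 3), c(2, 3), c(3, 1))
    adj[[2, 2]] <- co(c(1, 1), c(3, 3), c(1, 3), c(3, 1))
    adj[[2, 3]] <- -co(c(1, 1), c(2, 3), c(1, 3), c(2, 1))
    adj[[3, 1]] <- co(c(2, 1), c(3, 2), c(2, 2), c(3, 1))
    adj[[3, 2]] <- -co(c(1, 1), c(3, 2), c(1, 2), c(3, 1))
    adj[[3, 3]] <- co(c(1, 1), c(2, 2), c(1, 2), c(2, 1))
  } else {
    stop("negll_lowrank supports q = 2 or 3")
  }
  if (any(detM <= 0)) return(1e10)
  # g = adj(M) c, then quad correction c' V0 g / det
  g <- vector("list", q)
  for (j in seq_len(q)) {
    acc <- 0
    for (k in seq_len(q)) acc <- acc + adj[[j, k]] * st$Cmat[, k]
    g[[j]] <- acc
  }
  cV0g <- 0
  for (j in seq_len(q)) for (k in seq_len(q)) {
    if (V0[j, k] != 0) cV0g <- cV0g + V0[j, k] * st$Cmat[, j] * g[[k]]
  }
  logdet <- st$mivec * log(s2) + log(detM)
  quad <- st$dvec / s2 - cV0g / (detM * s2^2)
  val <- 0.5 * sum(logdet + quad)
  if (!is.finite(val)) 1e10 else val
}

# ML fit of the quadratic-polynomial (random intercept + slope) null.
fit_null_quadratic <- function(dat, ctrl) {
  st <- lowrank_stats(dat, q = 2)
  fit_quadratic_from_stats(st, null_quadratic_starts(dat), ctrl)
}

# Core optimizer over (log-Cholesky of V0, log sigma2) given sufficient
# statistics; `starts` is a list of 4-vectors in parameter space.
fit_quadratic_from_stats <- function(st, starts, ctrl) {
  obj <- function(par) {
    L <- matrix(c(exp(par[1]), par[2], 0, exp(par[3])), 2, 2)
    negll_lowrank(tcrossprod(L), exp(par[4]), st)
  }
  best <- NULL
  for (p0 in starts) {
    o <- tryCatch(
      stats::nlminb(p0, obj, control = list(rel.tol = ctrl$rel.tol,
                                            iter.max = ctrl$iter.max),
                    lower = rep(-18, 4), upper = rep(18, 4)),
      error = function(e) NULL)
    if (!is.null(o) && (is.null(best) || o$objective < best$objective)) {
      best <- o
    }
  }
  if (is.null(best)) {
    stop_covgof("null model optimization failed from all starts",
                "covgof_fit_error")
  }
  L <- matrix(c(exp(best$par[1]), best$par[2], 0, exp(best$par[3])), 2, 2)
  null_cov_fit("quadratic_polynomial", V0 = tcrossprod(L),
               sigma2 = exp(best$par[4]),
               loglik = -best$objective,
               converged = best$convergence == 0)
}

# Recompute the response-dependent statistics (C, d) for new values on a
# fixed design whose A and m are already in `st`; `Zs` are the per-subject
# design matrices [1, t].
update_lowrank_stats <- function(st, Zs, values) {
  for (i in seq_along(values)) {
    st$Cmat[i, ] <- crossprod(Zs[[i]], values[[i]])
    st$dvec[i] <- sum(values[[i]]^2)
  }
  st
}

# Parameter-space representation of a fitted quadratic null, used as a
# warm start when refitting on bootstrap data.
par_from_fit <- function(fit) {
  L <- t(chol(fit$V0 + diag(1e-8, 2)))
  c(log(L[1, 1]), L[2, 1], log(L[2, 2]), log(max(fit$sigma2, 1e-8)))
}

# Two starting points: pooled-variance split, and a moment start from
# per-subject OLS intercept/slope estimates.
null_quadratic_starts <- function(dat) {
  v <- stats::var(unlist(lapply(dat, `[[`, "values")))
  if (!is.finite(v) || v <= 0) v <- 1
  s1 <- c(0.5 * log(v / 2), 0, 0.5 * log(v / 2), log(v / 2))
  starts <- list(s1)
  ok <- vapply(dat, function(s) {
    length(s$times) >= 3 && length(unique(s$times)) >= 2
  }, TRUE)
  if (sum(ok) >= 10) {
    coefs <- t(vapply(dat[ok], function(s) {
      stats::coef(stats::lm.fit(cbind(1, s$times), s$values))
    }, numeric(2)))
    resvar <- mean(vapply(dat[ok], function(s) {
      r <- stats::lm.fit(cbind(1, s$times), s$values)$residuals
      sum(r^2) / max(length(r) - 2, 1)
    }, 1))
    Vm <- stats::cov(coefs)
    ee <- eigen((Vm + t(Vm)) / 2, symmetric = TRUE)
    Vm <- ee$vectors %*% (pmax(ee$values, v * 1e-3) * t(ee$vectors))
    L <- t(chol(Vm))
    starts <- c(starts, list(c(log(L[1, 1]), L[2, 1], log(L[2, 2]),
                               log(max(resvar, v * 1e-3)))))
  }
  starts
}

# Dense-likelihood machinery for the squared-exponential family.
negll_dense <- function(dat, fit) {
  s <- 0
  for (sub in dat) {
    G <- outer(sub$times, sub$times,
               function(a, b) eval_null_cov(fit, a, b))
    Vi <- G + diag(fit$sigma2, length(sub$times))
    ch <- tryCatch(chol(Vi), error = function(e) NULL)
    if (is.null(ch)) return(1e10)
    s <- s + 0.5 * (2 * sum(log(diag(ch))) +
                      sum(backsolve(ch, sub$values, transpose = TRUE)^2))
  }
  if (!is.finite(s)) 1e10 else s
}

fit_null_sqexp <- function(dat, ctrl) {
  v <- stats::var(unlist(lapply(dat, `[[`, "values")))
  if (!is.finite(v) || v <= 0) v <- 1
  rng <- range(unlist(lapply(dat, `[[`, "times")))
  obj <- function(par) {
    fit <- null_cov_fit("squared_exponential", theta = exp(par[1]),
                        delta = exp(par[2]), sigma2 = exp(par[3]))
    negll_dense(dat, fit)
  }
  p0 <- c(log(v / 2), log(diff(rng) / 4), log(v / 2))
  o <- stats::nlminb(p0, obj, control = list(rel.tol = ctrl$rel.tol,
                                             iter.max = ctrl$iter.max),
                     lower = rep(-18, 3), upper = rep(18, 3))
  null_cov_fit("squared_exponential", theta = exp(o$par[1]),
               delta = exp(o$par[2]), sigma2 = exp(o$par[3]),
               loglik = -o$objective, converged = o$convergence == 0)
}
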