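#' Cubic B-spline basis for covariance smoothing
#'
#' Builds an open (clamped) B-spline basis of dimension `H` on the domain,
#' with equally spaced interior knots and full endpoint knot multiplicity.
#' The default is `H = 10` cubic B-splines per axis, so a cubic basis has
#' `H - 4` interior knots.  The basis satisfies the partition of unity
#' \eqn{\sum_h B_h(t) = 1} and each \eqn{B_h \ge 0} has local support.
#' The Gram matrix of inner products \eqn{\int_a^b B_h B_{h'}\,dt},
#' needed for Hilbert-Schmidt norms, is computed at build time by
#' Gauss-Legendre quadrature on each inter-knot interval, exact for the
#' polynomial degree.
#'
#' @param domain numeric `c(a, b)`, `a < b`.
#' @param H number of basis functions per axis (at least `degree + 1`).
#' @param degree spline degree (default cubic).
#' @return an object of class `cov_basis`.
#' @examples
#' b <- build_basis(c(-1, 1), H = 10)
#' rowSums(eval_basis(b, c(-1, 0, 1)))  # all 1
#' @export
build_basis <- function(domain, H = 10L, degree = 3L) {
  domain <- as.numeric(domain)
  if (length(domain) != 2 || domain[1] >= domain[2]) {
    stop_covgof("domain must be c(a, b) with a < b", "covgof_domain_error")
  }
  if (H < degree + 1) {
    stop_covgof(sprintf("H must be at least %d for degree %d", degree + 1,
                        degree), "covgof_config_error")
  }
  breaks <- seq(domain[1], domain[2], length.out = H - degree + 1)
  interior <- if (length(breaks) > 2) breaks[-c(1, length(breaks))] else
    numeric(0)
  out <- list(domain = domain, H = as.integer(H), degree = as.integer(degree),
              interior = interior, breaks = breaks)
  class(out) <- "cov_basis"
  out$gram <- basis_gram(out)
  out
}

#' @export
print.cov_basis <- function(x, ...) {
  cat(sprintf(
    "<cov_basis> %d B-splines of degree %d on [%g, %g], %d interior knots\n",
    x$H, x$degree, x$domain[1], x$domain[2], length(x$interior)))
  invisible(x)
}

#' Evaluate the univariate basis
#'
#' @param basis a [build_basis()] result.
#' @param x numeric vector of points in the domain.
#' @return a `length(x)` by `H` matrix of basis values.
#' @export
eval_basis <- function(basis, x) {
  stopifnot(inherits(basis, "cov_basis"))
  B <- splines::bs(x, knots = basis$interior, degree = basis$degree,
                   intercept = TRUE, Boundary.knots = basis$domain)
  matrix(as.numeric(B), nrow = length(x))
}

# Gauss-Legendre nodes/weights on [-1, 1] via the Golub-Welsch Jacobi
# matrix; exact for polynomials of degree 2k - 1.
gauss_legendre <- function(k) {
  if (k == 1) return(list(x = 0, w = 2))
  j <- seq_len(k - 1)
  b <- j / sqrt(4 * j^2 - 1)
  J <- matrix(0, k, k)
  J[cbind(j, j + 1)] <- b
  J[cbind(j + 1, j)] <- b
  ee <- eigen(J, symmetric = TRUE)
  list(x = ee$values, w = 2 * ee$vectors[1, ]^2)
}

# Gram matrix of basis inner products over the domain.
basis_gram <- function(basis) {
  gl <- gauss_legendre(basis$degree + 1)
  M <- matrix(0, basis$H, basis$H)
  br <- basis$breaks
  for (i in seq_len(length(br) - 1)) {
    half <- (br[i + 1] - br[i]) / 2
    xs <- br[i] + half * (gl$x + 1)
    B <- eval_basis(basis, xs)
    M <- M + crossprod(B * (gl$w * half), B)
  }
  (M + t(M)) / 2
}

#' Symmetric tensor-product covariance surfaces
#'
#' A `cov_surface` represents a bivariate covariance estimate
#' \eqn{G(t,t') = \sum_{h,\ell} \theta_{h\ell} B_h(t) B_\ell(t')} with an
#' exactly symmetric coefficient matrix.  Use [eval_cov_surface()] or
#' `predict()` to evaluate it.
#'
#' @param basis a `cov_basis`.
#' @param theta `H` by `H` coefficient matrix (symmetrized).
#' @return an object of class `cov_surface`.
#' @export
cov_surface <- function(basis, theta) {
  stopifnot(inherits(basis, "cov_basis"),
            is.matrix(theta), all(dim(theta) == basis$H))
  out <- list(basis = basis, theta = (theta + t(theta)) / 2)
  class(out) <- "cov_surface"
  out
}

#' @export
print.cov_surface <- function(x, ...) {
  cat(sprintf("<cov_surface> %d x %d symmetric tensor B-spline coefficients\n",
              x$basis$H, x$basis$H))
  invisible(x)
}

#' Evaluate a covariance surface on a grid
#'
#' @param surface a `cov_surface`.
#' @param t,t2 numeric vectors; the surface is evaluated at all pairs,
#'   returning a `length(t)` by `length(t2)` matrix.  `t2` defaults to `t`.
#' @return a matrix of covariances \eqn{G(t, t')}.
#' @export
eval_cov_surface <- function(surface, t, t2 = t) {
  stopifnot(inherits(surface, "cov_surface"))
  B1 <- eval_basis(surface$basis, t)
  B2 <- eval_basis(surface$basis, t2)
  B1 %*% surface$theta %*% t(B2)
}

#' @export
predict.cov_surface <- function(object, t, t2 = t, ...) {
  eval_cov_surface(object, t, t2)
}

#' Nonparametric covariance estimation by symmetric tensor-product least squares
#'
#' Estimates the covariance surface by minimizing
#' \deqn{\sum_i \sum_{1 \le j \ne j' \le m_i}
#'   \left(\tilde Y_{ij}\tilde Y_{ij'} - \sum_{h,\ell}
#'   \theta_{h\ell} B_h(t_{ij}) B_\ell(t_{ij'})\right)^2}
#' over symmetric coefficient matrices \eqn{\theta_{h\ell} =
#' \theta_{\ell h}}.  Only off-diagonal cross-products (ordered pairs with
#' \eqn{j \ne j'}; subjects with \eqn{m_i = 1} contribute nothing) enter,
#' so the measurement-error variance does not contaminate the surface.
#' Symmetry is imposed by reparameterization onto the
#' \eqn{H(H+1)/2} free upper-triangle coefficients, not by post-hoc
#' averaging, and no roughness penalty is applied: smoothness comes from
#' the small basis dimension.  The normal equations are accumulated in
#' Kronecker form per subject, so the pair-level design matrix is never
#' materialized.  A rank-deficient system is solved by minimum-norm least
#' squares with a warning.
#'
#' @param demeaned an `fd_demeaned` (or centred [fd_sample]).
#' @param basis a [build_basis()] result; defaults to `H = 10` cubic
#'   B-splines on the sample domain.
#' @param prep optional precomputed [cov_smooth_prep()]; supply it when
#'   fitting many response sets on the same design (as the bootstrap does).
#' @return a [cov_surface] estimate \eqn{\hat G_A}.
#' @export
smooth_cross_products <- function(demeaned,
                                  basis = build_basis(demeaned$domain),
                                  prep = NULL) {
  if (is.null(prep)) prep <- cov_smooth_prep(demeaned, basis)
  rhs <- rhs_from_values(prep, lapply(fd_split(demeaned), `[[`, "values"))
  cov_surface(prep$basis, solve_sym(prep, rhs))
}

#' Smooth a parametric null surface onto the tensor-product span
#'
#' Projects the fitted null covariance through exactly the same
#' least-squares smoother as [smooth_cross_products()]: the responses
#' \eqn{\tilde Y_{ij}\tilde Y_{ij'}} are replaced by
#' \eqn{\hat G_0(t_{ij}, t_{ij'})} over the identical pair set and design.
#' Comparing the smoothed alternative with this smoothed null (rather than
#' with \eqn{\hat G_0} itself) removes the smoothing bias shared by the
#' two estimates.
#'
#' @param fit a `null_cov_fit`.
#' @inheritParams smooth_cross_products
#' @return a [cov_surface] estimate \eqn{K\hat G_0}.
#' @export
smooth_null_surface <- function(fit, demeaned,
                                basis = build_basis(demeaned$domain),
                                prep = NULL) {
  stopifnot(inherits(fit, "null_cov_fit"))
  if (is.null(prep)) prep <- cov_smooth_prep(demeaned, basis)
  rhs <- rhs_from_null(prep, fit)
  cov_surface(prep$basis, solve_sym(prep, rhs))
}

#' Precompute the fixed-design part of the covariance smoother
#'
#' The pair set, per-subject basis evaluations and the (symmetric
#' parameterization of the) normal-equation matrix depend only on the
#' observation times, so they can be shared across bootstrap replicates
#' that reuse the original design points.
#'
#' @inheritParams smooth_cross_products
#' @return an opaque prep object accepted by [smooth_cross_products()],
#'   [smooth_null_surface()] and [bootstrap_replicate()].
#' @export
cov_smooth_prep <- function(demeaned, basis = build_basis(demeaned$domain)) {
  stopifnot(inherits(demeaned, "fd_sample"), inherits(basis, "cov_basis"))
  dat <- fd_split(demeaned)
  H <- basis$H
  p <- H * (H + 1) / 2
  mi <- vapply(dat, function(s) length(s$times), 1L)
  n_pairs <- sum(mi * (mi - 1))
  if (n_pairs < p) {
    stop_covgof(sprintf(
      "too few off-diagonal pairs (%d) for %d free coefficients", n_pairs, p),
      "covgof_insufficient_data_error")
  }
  Tm <- sym_duplication(H)
  XtX <- matrix(0, H * H, H * H)
  Bs <- vector("list", length(dat))
  Cis <- vector("list", length(dat))
  for (i in seq_along(dat)) {
    B <- eval_basis(basis, dat[[i]]$times)
    G <- crossprod(B)
    Ci <- row_outer(B)
    XtX <- XtX + (G %x% G) - crossprod(Ci)
    Bs[[i]] <- B
    Cis[[i]] <- Ci
  }
  XtX_sym <- crossprod(Tm, XtX %*% Tm)
  ch <- tryCatch(chol(XtX_sym), error = function(e) NULL)
  sv <- NULL
  if (is.null(ch)) {
    warning("rank-deficient covariance smoothing design; using minimum-norm least squares")
    sv <- svd(XtX_sym)
  }
  structure(list(basis = basis, times = lapply(dat, `[[`, "times"),
                 Bs = Bs, Cis = Cis, Tm = Tm, chol = ch, svd = sv,
                 n_pairs = n_pairs),
            class = "cov_smooth_prep")
}

# Rows of the "diagonal pair" design: row j is vec(b_j b_j').
row_outer <- function(B) {
  H <- ncol(B)
  B[, rep(seq_len(H), each = H), drop = FALSE] *
    B[, rep(seq_len(H), times = H), drop = FALSE]
}

# Duplication-style map from packed symmetric coefficients (upper triangle,
# h <= l) to vec(Theta).
sym_duplication <- function(H) {
  p <- H * (H + 1) / 2
  Tm <- matrix(0, H * H, p)
  idx <- 0
  for (l in seq_len(H)) for (h in seq_len(l)) {
    idx <- idx + 1
    Tm[(l - 1) * H + h, idx] <- 1
    Tm[(h - 1) * H + l, idx] <- 1
  }
  Tm
}

# Right-hand side of the normal equations for cross-product responses.
rhs_from_values <- function(prep, values) {
  H <- prep$basis$H
  rhs <- numeric(H * H)
  for (i in seq_along(values)) {
    y <- values[[i]]
    u <- crossprod(prep$Bs[[i]], y)
    rhs <- rhs + as.numeric(tcrossprod(u)) - drop(crossprod(prep$Cis[[i]], y^2))
  }
  drop(crossprod(prep$Tm, rhs))
}

# Right-hand side with responses G0(t_ij, t_ij') from a parametric null.
rhs_from_null <- function(prep, fit) {
  H <- prep$basis$H
  rhs <- numeric(H * H)
  for (i in seq_along(prep$times)) {
    t_i <- prep$times[[i]]
    G0 <- outer(t_i, t_i, function(a, b) eval_null_cov(fit, a, b))
    B <- prep$Bs[[i]]
    rhs <- rhs + as.numeric(crossprod(B, G0 %*% B)) -
      drop(crossprod(prep$Cis[[i]], diag(G0)))
  }
  drop(crossprod(prep$Tm, rhs))
}

# Solve the symmetric-parameterization normal equations; returns Theta.
solve_sym <- function(prep, rhs) {
  H <- prep$basis$H
  theta_sym <- if (!is.null(prep$chol)) {
    backsolve(prep$chol, backsolve(prep$chol, rhs, transpose = TRUE))
  } else {
    d <- prep$svd$d
    tol <- max(d) * 1e-10
    pos <- d > tol
    prep$svd$v[, pos, drop = FALSE] %*%
      ((crossprod(prep$svd$u[, pos, drop = FALSE], rhs)) / d[pos])
  }
  Theta <- matrix(0, H, H)
  idx <- 0
  for (l in seq_len(H)) for (h in seq_len(l)) {
    idx <- idx + 1
    Theta[h, l] <- theta_sym[idx]
    Theta[l, h] <- theta_sym[idx]
  }
  Theta
}

#' Estimate the measurement-error variance from the covariance diagonal
#'
#' The raw squared residuals \eqn{\tilde Y_{ij}^2} have expectation
#' \eqn{G(t_{ij}, t_{ij}) + \sigma^2}, so averaging their distance from
#' the fitted smooth diagonal estimates \eqn{\sigma^2}.  To mitigate
#' boundary effects only observations whose times fall in the middle 50%
#' of the domain, \eqn{[a + 0.25(b-a),\; a + 0.75(b-a)]}, are used.  A
#' negative average is floored at zero, since the estimate seeds bootstrap
#' noise.
#'
#' @param demeaned an `fd_demeaned` (or centred [fd_sample]).
#' @param ghat a [cov_surface], normally the [smooth_cross_products()]
#'   estimate.
#' @return \eqn{\hat\sigma^2 \ge 0}.
#' @export
estimate_noise_variance <- function(demeaned, ghat) {
  stopifnot(inherits(demeaned, "fd_sample"), inherits(ghat, "cov_surface"))
  a <- demeaned$domain[1]
  b <- demeaned$domain[2]
  lo <- a + 0.25 * (b - a)
  hi <- a + 0.75 * (b - a)
  keep <- demeaned$data$time >= lo & demeaned$data$time <= hi
  if (!any(keep)) {
    stop_covgof("no observations in the middle 50% of the domain",
                "covgof_insufficient_data_error")
  }
  tt <- demeaned$data$time[keep]
  B <- eval_basis(ghat$basis, tt)
  diag_fit <- rowSums((B %*% ghat$theta) * B)
  max(0, mean(demeaned$data$value[keep]^2 - diag_fit))
}
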