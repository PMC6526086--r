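#' Squared Hilbert-Schmidt distance between covariance surfaces
#'
#' For two surfaces on the same basis, computes
#' \deqn{\|A - B\|_{HS} = \int\!\!\int \{A(t,t') - B(t,t')\}^2\,dt\,dt'}
#' (the squared-integral form; no square root is taken).  With shared
#' coefficients the double integral is exact:
#' \eqn{\mathrm{vec}(D)^\top (M \otimes M) \mathrm{vec}(D)} where
#' \eqn{D} is the coefficient difference and \eqn{M} the basis Gram
#' matrix, itself computed by Gauss-Legendre quadrature exact for the
#' polynomial degree.
#'
#' @param A,B [cov_surface] objects sharing one basis.
#' @return a nonnegative number.
#' @export
hs_distance <- function(A, B) {
  stopifnot(inherits(A, "cov_surface"), inherits(B, "cov_surface"))
  ba <- A$basis
  bb <- B$basis
  if (ba$H != bb$H || ba$degree != bb$degree ||
      !isTRUE(all.equal(ba$breaks, bb$breaks))) {
    stop_covgof("surfaces must share the same basis", "covgof_basis_error")
  }
  hs_from_theta(A$theta - B$theta, ba$gram)
}

hs_from_theta <- function(D, M) {
  sum((M %*% D %*% M) * D)
}

#' Prepare all fitted components of the goodness-of-fit test
#'
#' Runs the full estimation pipeline on a sample: penalized-spline mean
#' fit, de-meaning, maximum-likelihood fit of the parametric null,
#' symmetric tensor-product smoothing of the off-diagonal cross-products
#' (\eqn{\hat G_A}), the diagonal-based noise variance
#' \eqn{\hat\sigma^2}, the smoothed null surface \eqn{K\hat G_0} and the
#' observed statistic \eqn{T_n = \|\hat G_A - K\hat G_0\|_{HS}}.  The
#' returned object also carries the fixed-design precomputations
#' (mean design, pair-set normal equations, per-subject random-effects
#' statistics) that make bootstrap replicates cheap, since every replicate
#' reuses the original time points.
#'
#' @param sample an [fd_sample].
#' @param H tensor-product basis dimension per axis (default 10).
#' @param mean_basis_dim,mean_selection mean-fit settings, see
#'   [fit_mean()].
#' @param family null covariance family, see [fit_null()].
#' @param control optimizer control passed to [fit_null()].
#' @return an object of class `gof_prep`; see [run_gof_test()] for the
#'   fields most users want.
#' @export
gof_prep <- function(sample, H = 10L, mean_basis_dim = 10L,
                     mean_selection = "reml",
                     family = "quadratic_polynomial", control = list()) {
  stopifnot(inherits(sample, "fd_sample"))
  mean_fit <- fit_mean(sample, basis_dim = mean_basis_dim,
                       selection = mean_selection)
  dm <- demean(sample, mean_fit)
  null_fit <- fit_null(dm, family = family, control = control)
  basis <- build_basis(sample$domain, H = H)
  sprep <- cov_smooth_prep(dm, basis)
  values <- lapply(fd_split(dm), `[[`, "values")
  ghat_alt <- cov_surface(basis, solve_sym(sprep, rhs_from_values(sprep, values)))
  ghat_null <- cov_surface(basis, solve_sym(sprep, rhs_from_null(sprep, null_fit)))
  sigma2_alt <- estimate_noise_variance(dm, ghat_alt)
  Tn <- hs_distance(ghat_alt, ghat_null)

  ids <- sample$data$subject
  idx <- split(seq_along(ids), factor(ids, levels = unique(ids)))
  Zs <- lapply(sprep$times, function(t) cbind(1, t))
  st <- if (null_fit$family == "quadratic_polynomial") {
    lowrank_stats(fd_split(dm), q = 2)
  } else NULL

  structure(list(
    sample = sample, demeaned = dm, mean_fit = mean_fit,
    null_fit = null_fit, basis = basis, sprep = sprep,
    ghat_alt = ghat_alt, ghat_null = ghat_null,
    sigma2_alt = sigma2_alt, sigma2_null = null_fit$sigma2,
    Tn = Tn, idx = idx, Zs = Zs, st = st,
    mu_fitted = mean_fit$fitted,
    ctrl = list(rel.tol = control$rel.tol %||% 1e-10,
                iter.max = control$iter.max %||% 500L),
    family = family
  ), class = "gof_prep")
}

#' One wild-bootstrap replicate of the test statistic
#'
#' Builds one bootstrap dataset at the original design points,
#' \eqn{Y^{(l)}_{ij} = \hat\mu(t_{ij}) + X^{(l)}_i(t_{ij}) +
#' \varepsilon^{(l)}_{ij}}, with \eqn{X^{(l)}_i} generated from the fitted
#' null model and \eqn{\varepsilon^{(l)}_{ij} \sim N(0, \hat\sigma^2)}
#' using the noise variance estimated under the alternative model.  The
#' mean is then re-estimated on the bootstrap data with the original
#' settings, both covariance models are refitted, and the replicate
#' statistic \eqn{T_n^{(l)}} is returned.
#'
#' @param prep a [gof_prep()] object.
#' @param seed substream seed for this replicate; identical seeds give
#'   identical replicates.
#' @return a single nonnegative number \eqn{T_n^{(l)}}.
#' @export
bootstrap_replicate <- function(prep, seed) {
  stopifnot(inherits(prep, "gof_prep"))
  set.seed(seed)
  n <- length(prep$idx)
  y <- numeric(nrow(prep$sample$data))
  sig <- sqrt(prep$sigma2_alt)
  if (prep$null_fit$family == "quadratic_polynomial") {
    bmat <- matrix(stats::rnorm(2 * n), n, 2) %*% sym_sqrt(prep$null_fit$V0)
    for (i in seq_len(n)) {
      t_i <- prep$sprep$times[[i]]
      x <- bmat[i, 1] + bmat[i, 2] * t_i
      y[prep$idx[[i]]] <- x + stats::rnorm(length(t_i), sd = sig)
    }
  } else {
    for (i in seq_len(n)) {
      t_i <- prep$sprep$times[[i]]
      x <- simulate_null_subject(prep$null_fit, t_i)
      y[prep$idx[[i]]] <- x + stats::rnorm(length(t_i), sd = sig)
    }
  }
  y <- y + prep$mu_fitted

  # re-estimate the mean on the bootstrap data (same basis and selection)
  mf <- refit_mean(prep$mean_fit$md, y,
                   selection = prep$mean_fit$selection,
                   sp = prep$mean_fit$lambda)
  res <- y - mf$fitted
  values <- lapply(prep$idx, function(ii) res[ii])

  null_l <- if (prep$null_fit$family == "quadratic_polynomial") {
    st <- update_lowrank_stats(prep$st, prep$Zs, values)
    fit_quadratic_from_stats(st, list(par_from_fit(prep$null_fit)),
                             prep$ctrl)
  } else {
    dm_l <- prep$demeaned
    dm_l$data$value <- res
    fit_null(dm_l, family = prep$null_fit$family, control = prep$ctrl)
  }
  theta_alt <- solve_sym(prep$sprep, rhs_from_values(prep$sprep, values))
  theta_null <- solve_sym(prep$sprep, rhs_from_null(prep$sprep, null_l))
  hs_from_theta(theta_alt - theta_null, prep$basis$gram)
}

#' Goodness-of-fit test of a parametric covariance function
#'
#' Tests whether the covariance of the latent process has the parametric
#' null form (by default the quadratic polynomial induced by a linear
#' random intercept and slope model) against a smooth nonparametric
#' alternative.  The statistic is the squared Hilbert-Schmidt distance
#' between the tensor-product spline estimate of the covariance and the
#' identically-smoothed parametric null estimate; its null distribution
#' is approximated by a wild (parametric) bootstrap that regenerates data
#' from the fitted null at the original design points, re-estimating every
#' component on each replicate.  The p-value is
#' \eqn{L^{-1}\sum_l \mathbb{I}(T_n^{(l)} > T_n)} with strict inequality
#' and no continuity correction, so a p-value of exactly 0 is possible.
#'
#' A replicate whose component fits fail is retried once on a fresh
#' substream and otherwise dropped (with a warning); the p-value
#' denominator is the number of successful replicates.
#'
#' @param sample an [fd_sample].
#' @param L number of bootstrap replicates (default 1000).
#' @param seed master seed; all replicate substreams derive from it.
#' @inheritParams gof_prep
#' @return an object of class `gof_test_result` with elements
#'   `Tn` (observed statistic), `boot_stats`, `p_value`, `L`
#'   (successful replicates), `n_failed`, `seed`, and the component fits
#'   (`mean_fit`, `null_fit`, `ghat_alt`, `ghat_null`, `sigma2_alt`,
#'   `sigma2_null`).
#' @examples
#' \donttest{
#' s <- simulate_dataset(sim_design(n = 40, m = 10, seed = 2))
#' r <- run_gof_test(s, L = 50, seed = 1)
#' r$p_value
#' }
#' @export
run_gof_test <- function(sample, L = 1000L, seed = 1L, H = 10L,
                         mean_basis_dim = 10L, mean_selection = "reml",
                         family = "quadratic_polynomial", control = list()) {
  if (L < 1) stop_covgof("L must be at least 1", "covgof_config_error")
  prep <- gof_prep(sample, H = H, mean_basis_dim = mean_basis_dim,
                   mean_selection = mean_selection, family = family,
                   control = control)
  stats_l <- rep(NA_real_, L)
  n_failed <- 0L
  for (l in seq_len(L)) {
    tl <- tryCatch(bootstrap_replicate(prep, derive_seed(seed, l)),
                   error = function(e) NA_real_)
    if (is.na(tl)) {
      tl <- tryCatch(bootstrap_replicate(prep, derive_seed(seed, l, 2L)),
                     error = function(e) NA_real_)
    }
    if (is.na(tl)) n_failed <- n_failed + 1L
    stats_l[l] <- tl
  }
  if (n_failed > 0) {
    warning(sprintf("%d of %d bootstrap replicates failed and were excluded",
                    n_failed, L))
  }
  ok <- stats_l[!is.na(stats_l)]
  if (length(ok) == 0) {
    stop_covgof("all bootstrap replicates failed", "covgof_fit_error")
  }
  out <- list(
    Tn = prep$Tn, boot_stats = ok,
    p_value = mean(ok > prep$Tn),
    L = length(ok), L_requested = as.integer(L), n_failed = n_failed,
    seed = as.integer(seed),
    mean_fit = prep$mean_fit, null_fit = prep$null_fit,
    ghat_alt = prep$ghat_alt, ghat_null = prep$ghat_null,
    sigma2_alt = prep$sigma2_alt, sigma2_null = prep$sigma2_null
  )
  class(out) <- "gof_test_result"
  out
}

#' @export
print.gof_test_result <- function(x, ...) {
  cat("Smoothing-based goodness-of-fit test of covariance\n")
  cat(sprintf("  null family: %s\n", x$null_fit$family))
  cat(sprintf("  Tn = %.6g,  bootstrap L = %d,  p-value = %.4g\n",
              x$Tn, x$L, x$p_value))
  cat(sprintf("  noise variance: %.4g (alternative diagonal), %.4g (null ML)\n",
              x$sigma2_alt, x$sigma2_null))
  if (x$n_failed > 0) {
    cat(sprintf("  note: %d replicates failed and were excluded\n",
                x$n_failed))
  }
  invisible(x)
}
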