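#' Smooth mean estimation for functional samples
#'
#' Fits the smooth mean function \eqn{\mu(t)} by penalized cubic regression
#' splines on the pooled observations \eqn{(t_{ij}, Y_{ij})}, with the
#' smoothing parameter chosen by REML (default) or GCV, or fixed by the
#' user.  The basis and penalty are constructed with
#' [mgcv::smoothCon()] (`bs = "cr"`), and the single smoothing parameter is
#' profiled out in closed form after a simultaneous diagonalisation of the
#' normal equations, which makes repeated refits on the same design (as in
#' the bootstrap, where every replicate reuses the original time points)
#' essentially free.  The fit coincides with `mgcv::gam(y ~ s(t, k, bs =
#' "cr"), method = "REML")` up to optimiser tolerance.
#'
#' @param sample an [fd_sample].
#' @param basis_dim spline basis dimension including the intercept
#'   (default 10).
#' @param selection smoothing-parameter selection: `"reml"`, `"gcv"` or
#'   `"fixed"`.
#' @param sp fixed smoothing parameter, required when
#'   `selection = "fixed"`.
#' @return an object of class `cov_mean_fit` with elements `beta`
#'   (coefficients), `lambda` (smoothing parameter), `fitted` (fitted
#'   values at the observed times, in data order) and the basis
#'   description.
#' @seealso [demean()]
#' @export
fit_mean <- function(sample, basis_dim = 10L,
                     selection = c("reml", "gcv", "fixed"), sp = NULL) {
  stopifnot(inherits(sample, "fd_sample"))
  selection <- match.arg(selection)
  md <- mean_design(sample$data$time, basis_dim)
  fit <- refit_mean(md, sample$data$value, selection = selection, sp = sp)
  out <- list(
    md = md, beta = fit$beta, lambda = fit$lambda,
    fitted = fit$fitted, selection = selection,
    basis_dim = basis_dim, domain = sample$domain
  )
  class(out) <- "cov_mean_fit"
  out
}

#' @export
print.cov_mean_fit <- function(x, ...) {
  cat(sprintf(
    "<cov_mean_fit> penalized cubic regression spline, k=%d, %s, lambda=%.4g\n",
    x$basis_dim, x$selection, x$lambda))
  invisible(x)
}

#' Evaluate a fitted mean function
#'
#' @param object a `cov_mean_fit`.
#' @param t numeric vector of evaluation times.
#' @param ... unused.
#' @return numeric vector \eqn{\hat\mu(t)}.
#' @export
predict.cov_mean_fit <- function(object, t, ...) {
  X <- cbind(1, mgcv::PredictMat(object$md$sm, data.frame(time = as.numeric(t))))
  drop(X %*% object$beta)
}

#' Subtract the fitted mean from a sample
#'
#' Produces the de-meaned data \eqn{\tilde Y_{ij} = Y_{ij} -
#' \hat\mu(t_{ij})} record for record.  The values used are the fitted
#' values of the mean fit at the observed times, so there is no
#' train/predict drift.
#'
#' @param sample an [fd_sample].
#' @param fit a [fit_mean()] result for this sample (defaults to fitting
#'   one with default settings).
#' @return an `fd_demeaned` object: an [fd_sample] whose values are
#'   residuals, with the mean fit attached as `$mean_fit`.
#' @export
demean <- function(sample, fit = fit_mean(sample)) {
  stopifnot(inherits(sample, "fd_sample"), inherits(fit, "cov_mean_fit"))
  mu <- if (length(fit$fitted) == nrow(sample$data)) fit$fitted else
    predict(fit, sample$data$time)
  out <- sample
  out$data$value <- sample$data$value - mu
  out$mean_fit <- fit
  class(out) <- c("fd_demeaned", "fd_sample")
  out
}

# ---- internal fast penalized-spline machinery --------------------------------

# Build the fixed-design part of the mean smoother: basis matrix, penalty,
# and the simultaneous diagonalisation used to profile the smoothing
# parameter.  Reused across bootstrap replicates (same times, new values).
mean_design <- function(times, basis_dim) {
  n <- length(times)
  if (n < basis_dim) {
    stop_covgof("fewer observations than mean basis functions",
                "covgof_insufficient_data_error")
  }
  n_unique <- length(unique(times))
  if (n_unique < 3) {
    stop_covgof("fewer than 3 distinct observation times; smooth mean not identifiable",
                "covgof_degenerate_design_error")
  }
  basis_dim <- min(basis_dim, n_unique)
  sm <- mgcv::smoothCon(mgcv::s(time, k = basis_dim, bs = "cr"),
                        data = data.frame(time = times),
                        absorb.cons = TRUE)[[1]]
  X <- cbind(1, sm$X)
  k <- ncol(X)
  S <- matrix(0, k, k)
  S[-1, -1] <- sm$S[[1]]
  R <- chol(crossprod(X) + diag(1e-10, k))
  Sh <- backsolve(R, t(backsolve(R, S, transpose = TRUE)), transpose = TRUE)
  ee <- eigen((Sh + t(Sh)) / 2, symmetric = TRUE)
  d <- pmax(ee$values, 0)
  pos <- d > max(d) * 1e-9
  list(sm = sm, X = X, R = R, U = ee$vectors, d = d, pos = pos,
       M_null = sum(!pos), n = n)
}

# Solve the penalized least squares problem for a new response vector,
# selecting lambda by the requested criterion.
refit_mean <- function(md, y, selection = "reml", sp = NULL) {
  z <- drop(crossprod(md$U, backsolve(md$R, crossprod(md$X, y),
                                      transpose = TRUE)))
  yty <- sum(y^2)
  n <- md$n
  d <- md$d
  pos <- md$pos
  M <- md$M_null
  crit <- switch(selection,
    reml = function(loglam) {
      lam <- exp(loglam)
      rsspen <- max(yty - sum(z^2 / (1 + lam * d)), 1e-300)
      sig2 <- rsspen / (n - M)
      0.5 * (sum(log1p(lam * d[pos])) - sum(pos) * loglam) +
        0.5 * (n - M) * log(sig2)
    },
    gcv = function(loglam) {
      lam <- exp(loglam)
      shrink <- 1 / (1 + lam * d)
      rss <- max(yty - 2 * sum(z^2 * shrink) + sum(z^2 * shrink^2), 1e-300)
      edf <- sum(shrink)
      n * rss / (n - edf)^2
    },
    fixed = NULL
  )
  if (selection == "fixed") {
    if (is.null(sp) || sp < 0) {
      stop_covgof("selection = 'fixed' requires a nonnegative sp",
                  "covgof_config_error")
    }
    lam <- sp
  } else {
    lam <- exp(stats::optimize(crit, c(-25, 30))$minimum)
  }
  beta <- backsolve(md$R, md$U %*% (z / (1 + lam * d)))
  list(beta = beta, lambda = lam, fitted = drop(md$X %*% beta))
}
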