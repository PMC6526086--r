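#' Simulation designs for irregular longitudinal data
#'
#' Describes one scenario of the study generator
#' \deqn{Y_{ij} = X_i(t_{ij}) + \varepsilon_{ij}, \qquad
#'       X_i(t) = b_{0i} + b_{1i} t + \Delta z_i(t),}
#' where \eqn{(b_{0i}, b_{1i})^\top \sim N(0, V_0)} with, by default, unit
#' intercept and slope variances and covariance \eqn{-0.5};
#' \eqn{\varepsilon_{ij} \sim N(0, \sigma^2)} with \eqn{\sigma = 1}; and the
#' mean function is identically zero.  The deviation \eqn{z_i} is either
#' * `"quadratic"`: \eqn{z_i(t) = b_{2i} t^2}, \eqn{b_{2i} \sim N(0, 1)}, or
#' * `"trigonometric"`: \eqn{z_i(t) = \xi_{i1}\sin(2\pi t) +
#'   \xi_{i2}\sin(4\pi t)} with \eqn{\xi_{ik} \sim N(0, 1)},
#'
#' scaled by the multiplier `delta`; `delta = 0` (or
#' `deviation = "none"`) gives the null model, whose covariance is the
#' quadratic polynomial \eqn{G_0(t,t') = \sigma_0^2 + \sigma_{01}(t + t') +
#' \sigma_1^2 t t'}.
#'
#' Observation times live on a grid of `grid_size` equally spaced points
#' (endpoints included) in `domain`.  When `m < grid_size` each subject's
#' `m` time points are drawn uniformly without replacement from the grid,
#' independently across subjects; when `m == grid_size` every subject is
#' observed at all grid points.
#'
#' @param n number of subjects.
#' @param m observations per subject (must not exceed `grid_size`).
#' @param delta nonnegative deviation multiplier \eqn{\Delta}.
#' @param deviation deviation type: `"none"`, `"quadratic"` or
#'   `"trigonometric"`.
#' @param grid_size number of grid points (default 80).
#' @param domain observation domain (default `c(-1, 1)`).
#' @param noise_sd residual standard deviation \eqn{\sigma} (default 1).
#' @param re_cov 2x2 random intercept/slope covariance \eqn{V_0}.
#' @param seed master seed; per-subject streams are derived from it so the
#'   dataset is reproducible under any generation order.
#' @return an object of class `sim_design`.
#' @export
sim_design <- function(n, m, delta = 0,
                       deviation = c("none", "quadratic", "trigonometric"),
                       grid_size = 80L, domain = c(-1, 1), noise_sd = 1,
                       re_cov = matrix(c(1, -0.5, -0.5, 1), 2, 2),
                       seed = 1L) {
  deviation <- match.arg(deviation)
  if (m > grid_size) {
    stop_covgof("m must not exceed grid_size", "covgof_design_error")
  }
  if (delta < 0 || noise_sd < 0) {
    stop_covgof("delta and noise_sd must be nonnegative", "covgof_design_error")
  }
  re_cov <- (re_cov + t(re_cov)) / 2
  ev <- eigen(re_cov, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10) {
    stop_covgof("re_cov must be positive semidefinite", "covgof_design_error")
  }
  if (delta > 0 && deviation == "none") {
    stop_covgof("delta > 0 requires a deviation type", "covgof_design_error")
  }
  out <- list(n = as.integer(n), m = as.integer(m), delta = delta,
              deviation = deviation, grid_size = as.integer(grid_size),
              domain = as.numeric(domain), noise_sd = noise_sd,
              re_cov = re_cov, seed = as.integer(seed))
  class(out) <- "sim_design"
  out
}

#' @export
print.sim_design <- function(x, ...) {
  cat(sprintf(
    "<sim_design> n=%d, m=%d, delta=%g (%s), grid=%d on [%g, %g], seed=%d\n",
    x$n, x$m, x$delta, x$deviation, x$grid_size, x$domain[1], x$domain[2],
    x$seed))
  invisible(x)
}

# Pointwise variance of the deviation process z_i(t).
deviation_variance <- function(t, deviation) {
  switch(deviation,
         none = rep(0, length(t)),
         quadratic = t^4,
         trigonometric = sin(2 * pi * t)^2 + sin(4 * pi * t)^2)
}

# Pointwise variance of X_i(t) = b0 + b1 t + Delta z_i(t).
process_variance <- function(t, design) {
  V <- design$re_cov
  V[1, 1] + 2 * V[1, 2] * t + V[2, 2] * t^2 +
    design$delta^2 * deviation_variance(t, design$deviation)
}

#' Simulate a dataset from a `sim_design`
#'
#' Generates one irregular longitudinal dataset according to the design.
#' Each subject's random-effect draws, grid subset and noise come from a
#' substream derived from the design seed and the subject index, so
#' identical designs produce bit-identical datasets.
#'
#' @param design a [sim_design].
#' @return an [fd_sample] with subjects `"1", ..., "n"`.
#' @examples
#' d <- sim_design(n = 20, m = 10, seed = 7)
#' s <- simulate_dataset(d)
#' n_obs(s)
#' @export
simulate_dataset <- function(design) {
  stopifnot(inherits(design, "sim_design"))
  grid <- seq(design$domain[1], design$domain[2],
              length.out = design$grid_size)
  cl <- chol(design$re_cov + diag(1e-12, 2))
  subj <- vector("list", design$n)
  for (i in seq_len(design$n)) {
    set.seed(derive_seed(design$seed, i))
    t_i <- if (design$m == design$grid_size) grid else
      sort(sample(grid, design$m, replace = FALSE))
    b <- drop(crossprod(cl, stats::rnorm(2)))
    x <- b[1] + b[2] * t_i
    if (design$delta > 0) {
      z <- switch(design$deviation,
                  quadratic = stats::rnorm(1) * t_i^2,
                  trigonometric = stats::rnorm(1) * sin(2 * pi * t_i) +
                    stats::rnorm(1) * sin(4 * pi * t_i),
                  none = 0)
      x <- x + design$delta * z
    }
    y <- x + stats::rnorm(design$m, sd = design$noise_sd)
    subj[[i]] <- list(t = t_i, y = y)
  }
  fd_sample(
    subject = rep(as.character(seq_len(design$n)),
                  each = design$m),
    time = unlist(lapply(subj, `[[`, "t")),
    value = unlist(lapply(subj, `[[`, "y")),
    domain = design$domain
  )
}

#' Size of the deviation from the null covariance
#'
#' Computes the deviation measure
#' \deqn{\Delta^2 \int_T \mathrm{Var}\{z_i(t)\} / \mathrm{Var}\{X_i(t)\}\,dt,}
#' where the denominator includes the deviation term itself.  This is the
#' natural x-axis for power curves: it is zero under the null and grows
#' monotonically with `delta`.  Evaluated by composite Simpson quadrature
#' on 2001 nodes (the integrand is smooth and bounded whenever the
#' random-effect covariance is positive definite on the domain).
#'
#' @param design a [sim_design].
#' @return a single nonnegative number.
#' @examples
#' deviation_size(sim_design(100, 20, delta = 1, deviation = "quadratic"))
#' @export
deviation_size <- function(design) {
  stopifnot(inherits(design, "sim_design"))
  if (design$delta == 0 || design$deviation == "none") return(0)
  f <- function(t) {
    design$delta^2 * deviation_variance(t, design$deviation) /
      process_variance(t, design)
  }
  simpson(f, design$domain[1], design$domain[2], 2001L)
}
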