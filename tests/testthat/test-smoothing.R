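test_that("the clamped B-spline basis has the textbook structure", {
  b <- build_basis(c(-1, 1), H = 10)
  expect_length(b$interior, 6)
  set.seed(51)
  tt <- c(-1, 1, runif(100, -1, 1))
  B <- eval_basis(b, tt)
  expect_equal(rowSums(B), rep(1, length(tt)), tolerance = 1e-12)
  expect_true(all(B >= -1e-14))
  # clamped end condition
  expect_equal(eval_basis(b, -1)[1, ], c(1, rep(0, 9)))
  expect_error(build_basis(c(-1, 1), H = 3), class = "covgof_config_error")
})

test_that("the basis Gram matrix integrates products exactly", {
  b <- build_basis(c(-1, 1), H = 6)
  tt <- seq(-1, 1, length.out = 4001)
  B <- eval_basis(b, tt)
  M_trap <- crossprod(B[-1, ] + B[-nrow(B), ]) / 4 * diff(tt[1:2])
  expect_equal(b$gram, M_trap, tolerance = 1e-6)
})

test_that("the tensor-product smoother matches a brute-force pair-level solve", {
  set.seed(52)
  s <- null_model_sample(n = 5, m = 4, seed = 52)
  basis <- build_basis(c(-1, 1), H = 4)
  fit <- smooth_cross_products(s, basis)
  expect_equal(fit$theta, t(fit$theta))  # exactly symmetric
  expect_equal(fit$theta, brute_force_smoother(s, basis), tolerance = 1e-8)

  # a larger irregular instance against the same oracle
  s2 <- null_model_sample(n = 12, m = 6, seed = 53)
  basis2 <- build_basis(c(-1, 1), H = 5)
  expect_equal(smooth_cross_products(s2, basis2)$theta,
               brute_force_smoother(s2, basis2), tolerance = 1e-8)
})

test_that("surfaces in the tensor span are reproduced exactly", {
  # the quadratic-polynomial null lies in the cubic tensor span, so the
  # smoothed null equals the null itself everywhere
  s <- null_model_sample(n = 30, m = 8, seed = 54)
  basis <- build_basis(c(-1, 1), H = 10)
  f <- null_cov_fit(V0 = matrix(c(1.3, -0.4, -0.4, 0.8), 2), sigma2 = 1)
  sm <- smooth_null_surface(f, s, basis)
  tg <- seq(-1, 1, length.out = 41)
  expect_equal(eval_cov_surface(sm, tg, tg),
               outer(tg, tg, function(a, b) eval_null_cov(f, a, b)),
               tolerance = 1e-8)

  f0 <- null_cov_fit(V0 = matrix(0, 2, 2), sigma2 = 0)
  sm0 <- smooth_null_surface(f0, s, basis)
  expect_equal(max(abs(eval_cov_surface(sm0, tg, tg))), 0, tolerance = 1e-10)
})

test_that("the smoother is invariant to subject relabelling", {
  s <- null_model_sample(n = 15, m = 6, seed = 55)
  perm <- order(rev(seq_len(nrow(s$data))))
  s_perm <- fd_sample(paste0("x", s$data$subject[perm]), s$data$time[perm],
                      s$data$value[perm], domain = s$domain)
  basis <- build_basis(c(-1, 1), H = 6)
  expect_equal(smooth_cross_products(s, basis)$theta,
               smooth_cross_products(s_perm, basis)$theta, tolerance = 1e-9)
})

test_that("too few off-diagonal pairs is an error", {
  s <- fd_sample(rep(1:4, each = 2), rep(c(-0.5, 0.5), 4), rnorm(8),
                 domain = c(-1, 1))
  expect_error(cov_smooth_prep(s, build_basis(c(-1, 1), H = 10)),
               class = "covgof_insufficient_data_error")
})

test_that("the diagonal-gap noise estimator returns the constant offset", {
  basis <- build_basis(c(-1, 1), H = 6)
  ghat <- cov_surface(basis, diag(6) * 0.5 + 0.2)
  set.seed(56)
  tt <- runif(200, -1, 1)
  diag_vals <- diag(eval_cov_surface(ghat, tt, tt))
  for (c0 in c(0.7, 0.05)) {
    s <- fd_sample(rep(1:20, each = 10), tt, sqrt(diag_vals + c0),
                   domain = c(-1, 1))
    expect_equal(estimate_noise_variance(s, ghat), c0, tolerance = 1e-10)
  }
  # floor at zero when squared residuals sit below the fitted diagonal
  s0 <- fd_sample(rep(1:20, each = 10), tt, rep(0, 200), domain = c(-1, 1))
  expect_identical(estimate_noise_variance(s0, ghat), 0)
  # only the middle 50% should be used: no qualifying points is an error
  edge <- fd_sample(1:6, c(rep(-0.9, 3), rep(0.95, 3)), rnorm(6),
                    domain = c(-1, 1))
  expect_error(estimate_noise_variance(edge, ghat),
               class = "covgof_insufficient_data_error")
})

test_that("the noise variance is recovered under the standard design", {
  s <- simulate_dataset(sim_design(n = 500, m = 40, seed = 57))
  dm <- demean(s)
  ghat <- smooth_cross_products(dm)
  expect_gt(estimate_noise_variance(dm, ghat), 0.8)
  expect_lt(estimate_noise_variance(dm, ghat), 1.2)
})
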