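test_that("penalized mean fit agrees with the mgcv reference", {
  set.seed(31)
  n <- 600
  tt <- runif(n, -1, 1)
  yy <- sin(2 * tt) + 0.3 * tt^2 + rnorm(n, sd = 0.4)
  s <- fd_sample(rep(1:60, each = 10), tt, yy, domain = c(-1, 1))
  fit <- fit_mean(s, basis_dim = 10, selection = "reml")
  g <- mgcv::gam(yy ~ s(tt, k = 10, bs = "cr"), method = "REML")
  expect_equal(unname(fit$fitted), unname(fitted(g)), tolerance = 1e-5)
  # predictions at observed times equal the fitted values used in demeaning
  expect_equal(predict(fit, tt), fit$fitted, tolerance = 1e-10)
})

test_that("constants are reproduced exactly and huge penalties give the OLS line", {
  s <- fd_sample(rep(1:5, each = 6), rep(seq(-1, 1, length.out = 6), 5),
                 rep(3.7, 30))
  fit <- fit_mean(s)
  expect_equal(predict(fit, c(-0.9, 0, 0.4)), rep(3.7, 3), tolerance = 1e-8)

  set.seed(32)
  tt <- runif(80, -1, 1)
  yy <- 1 + 2 * tt + rnorm(80)
  s2 <- fd_sample(rep(1:8, each = 10), tt, yy, domain = c(-1, 1))
  fit2 <- fit_mean(s2, selection = "fixed", sp = 1e9)
  ols <- lm(yy ~ tt)
  expect_equal(predict(fit2, c(-0.5, 0.5)),
               unname(predict(ols, data.frame(tt = c(-0.5, 0.5)))),
               tolerance = 1e-4)
})

test_that("demeaning is an exact inverse and centres a flat design", {
  set.seed(33)
  s <- simulate_dataset(sim_design(n = 50, m = 12, seed = 33))
  fit <- fit_mean(s)
  dm <- demean(s, fit)
  expect_s3_class(dm, "fd_demeaned")
  expect_equal(dm$data$value + predict(fit, dm$data$time), s$data$value,
               tolerance = 1e-10)
  # zero-mean generator: fitted mean should be small vs pooled SD
  big <- simulate_dataset(sim_design(n = 100, m = 20, seed = 34))
  mf <- fit_mean(big)
  tg <- seq(-1, 1, length.out = 101)
  expect_lt(max(abs(predict(mf, tg))), 0.15)
  # residuals are centred
  expect_lt(abs(mean(demean(big, mf)$data$value)), 0.02)
})

test_that("mean fit is invariant to subject ordering", {
  set.seed(35)
  s <- simulate_dataset(sim_design(n = 30, m = 8, seed = 35))
  perm <- order(rev(as.integer(s$data$subject)))
  s_perm <- fd_sample(s$data$subject[perm], s$data$time[perm],
                      s$data$value[perm], domain = s$domain)
  f1 <- fit_mean(s)
  f2 <- fit_mean(s_perm)
  tg <- seq(-1, 1, length.out = 21)
  expect_equal(predict(f1, tg), predict(f2, tg), tolerance = 1e-6)
})

test_that("degenerate designs are rejected", {
  s <- fd_sample(1:4, c(0, 1, 2, 3), rnorm(4))
  expect_error(fit_mean(s, basis_dim = 10),
               class = "covgof_insufficient_data_error")
  s2 <- fd_sample(rep(1:6, each = 2), rep(0.5, 12), rnorm(12),
                  domain = c(0, 1))
  expect_error(fit_mean(s2), class = "covgof_degenerate_design_error")
})
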