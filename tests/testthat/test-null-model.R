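test_that("null covariance evaluation is the printed quadratic polynomial", {
  f <- null_cov_fit(V0 = matrix(c(1, -0.5, -0.5, 1), 2), sigma2 = 1)
  expect_equal(eval_null_cov(f, 1, 1), 1)      # 1 - 0.5*2 + 1
  expect_equal(eval_null_cov(f, 0, 0), 1)      # sigma_0^2
  expect_equal(eval_null_cov(f, 0.3, -0.8), 1 - 0.5 * (0.3 - 0.8) - 0.24)
  fe <- null_cov_fit("squared_exponential", theta = 2.5, delta = 0.7)
  expect_equal(eval_null_cov(fe, 0.4, 0.4), 2.5)
  # symmetry for both families
  set.seed(41)
  a <- runif(20, -1, 1); b <- runif(20, -1, 1)
  expect_equal(eval_null_cov(f, a, b), eval_null_cov(f, b, a))
  expect_equal(eval_null_cov(fe, a, b), eval_null_cov(fe, b, a))
})

test_that("the Woodbury likelihood equals a dense per-subject Cholesky oracle", {
  s <- null_model_sample(n = 40, m = 7, seed = 42)
  for (pars in list(list(V0 = matrix(c(1, -0.5, -0.5, 1), 2), s2 = 1),
                    list(V0 = matrix(c(2, 0.3, 0.3, 0.5), 2), s2 = 0.4))) {
    f <- null_cov_fit(V0 = pars$V0, sigma2 = pars$s2)
    expect_equal(null_loglik(s, f), naive_null_loglik(s, f),
                 tolerance = 1e-10)
  }
})

test_that("maximum likelihood recovers the generating parameters", {
  s <- null_model_sample(n = 2000, m = 20, seed = 43)
  fit <- fit_null(s)
  expect_true(fit$converged)
  expect_equal(fit$V0[1, 1], 1, tolerance = 0.1)
  expect_equal(fit$V0[1, 2], -0.5, tolerance = 0.1)
  expect_equal(fit$V0[2, 2], 1, tolerance = 0.1)
  expect_equal(fit$sigma2, 1, tolerance = 0.1)

  # optimality: at least as good as the truth, and any +/-10% single-parameter
  # perturbation of the optimum decreases the objective
  truth <- null_cov_fit(V0 = matrix(c(1, -0.5, -0.5, 1), 2), sigma2 = 1)
  expect_gte(fit$loglik, null_loglik(s, truth))
  expect_equal(fit$loglik, null_loglik(s, fit), tolerance = 1e-8)
  for (perturb in list(c(1, 1), c(2, 2), c(1, 2), "sigma2")) {
    for (fac in c(0.9, 1.1)) {
      V <- fit$V0
      s2 <- fit$sigma2
      if (identical(perturb, "sigma2")) s2 <- s2 * fac
      else {
        V[perturb[1], perturb[2]] <- V[perturb[1], perturb[2]] * fac
        V[perturb[2], perturb[1]] <- V[perturb[1], perturb[2]]
      }
      expect_lt(null_loglik(s, null_cov_fit(V0 = V, sigma2 = s2)),
                fit$loglik)
    }
  }
})

test_that("an independent mixed-model fitter cannot beat the ML optimum", {
  s <- null_model_sample(n = 150, m = 10, seed = 44)
  fit <- fit_null(s)
  df <- as.data.frame(s$data)
  lf <- nlme::lme(value ~ 1, random = ~ time | subject, data = df,
                  method = "ML")
  Vl <- matrix(as.numeric(nlme::getVarCov(lf)), 2)
  fl <- null_cov_fit(V0 = Vl, sigma2 = lf$sigma^2)
  expect_gte(fit$loglik + 1e-6, null_loglik(s, fl))
  # and the two fits should be close on well-identified data
  expect_equal(fit$V0, Vl, tolerance = 0.15)
  expect_equal(fit$sigma2, lf$sigma^2, tolerance = 0.1)
})

test_that("fitting is invariant to subject order and flags degenerate input", {
  s <- null_model_sample(n = 60, m = 6, seed = 45)
  perm <- order(rev(seq_len(nrow(s$data))))
  s_perm <- fd_sample(s$data$subject[perm], s$data$time[perm],
                      s$data$value[perm], domain = s$domain)
  expect_equal(fit_null(s)$loglik, fit_null(s_perm)$loglik, tolerance = 1e-6)

  singles <- fd_sample(1:30, runif(30, -1, 1), rnorm(30), domain = c(-1, 1))
  expect_error(fit_null(singles), class = "covgof_identifiability_error")
})

test_that("null-model simulation has the advertised trajectory law", {
  f <- null_cov_fit(V0 = matrix(c(1, -0.5, -0.5, 1), 2), sigma2 = 1)
  tt <- c(-1, -0.25, 0.5, 1)
  x <- simulate_null_subject(f, tt, seed = 46)
  # exactly linear in t
  slope <- (x[2] - x[1]) / (tt[2] - tt[1])
  expect_equal(x, x[1] + slope * (tt - tt[1]), tolerance = 1e-12)

  f0 <- null_cov_fit(V0 = matrix(0, 2, 2), sigma2 = 0)
  expect_equal(simulate_null_subject(f0, tt, seed = 47), rep(0, 4))

  # Monte-Carlo covariance at a fixed pair matches eval_null_cov
  set.seed(48)
  draws <- t(vapply(1:20000, function(i) simulate_null_subject(f, c(-0.4, 0.7)),
                    numeric(2)))
  expect_equal(cov(draws[, 1], draws[, 2]), eval_null_cov(f, -0.4, 0.7),
               tolerance = 0.05)

  # generic-family route through the symmetric matrix square root
  fe <- null_cov_fit("squared_exponential", theta = 1.3, delta = 0.8)
  set.seed(49)
  de <- t(vapply(1:20000, function(i) simulate_null_subject(fe, c(0.1, 0.3)),
                 numeric(2)))
  expect_equal(cov(de[, 1], de[, 2]), eval_null_cov(fe, 0.1, 0.3),
               tolerance = 0.06)
})

test_that("the squared-exponential family fits by the same ML machinery", {
  set.seed(50)
  fe_true <- null_cov_fit("squared_exponential", theta = 1.5, delta = 0.9)
  n <- 250; m <- 6
  subj <- lapply(seq_len(n), function(i) {
    tt <- sort(runif(m, -1, 1))
    x <- simulate_null_subject(fe_true, tt) + rnorm(m, sd = sqrt(0.5))
    list(t = tt, x = x)
  })
  s <- fd_sample(rep(seq_len(n), each = m),
                 unlist(lapply(subj, `[[`, "t")),
                 unlist(lapply(subj, `[[`, "x")), domain = c(-1, 1))
  fit <- fit_null(s, family = "squared_exponential")
  expect_true(fit$converged)
  expect_equal(fit$theta, 1.5, tolerance = 0.35)
  expect_equal(fit$delta, 0.9, tolerance = 0.35)
  expect_equal(fit$sigma2, 0.5, tolerance = 0.25)
})
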