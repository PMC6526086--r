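test_that("the Hilbert-Schmidt statistic matches closed forms and a grid oracle", {
  basis <- build_basis(c(-1, 1), H = 7)
  set.seed(61)
  A <- cov_surface(basis, matrix(rnorm(49), 7))
  expect_identical(hs_distance(A, A), 0)

  # constant difference c over [-1,1]^2 integrates to 4 c^2
  c0 <- 0.63
  B <- cov_surface(basis, A$theta + c0)
  expect_equal(hs_distance(A, B), 4 * c0^2, tolerance = 1e-10)

  # 2-D Simpson quadrature oracle on a ~400 x 400 grid
  for (rep in 1:3) {
    D1 <- cov_surface(basis, matrix(rnorm(49), 7))
    D2 <- cov_surface(basis, matrix(rnorm(49), 7))
    tg <- seq(-1, 1, length.out = 401)
    h <- diff(tg[1:2])
    f <- (eval_cov_surface(D1, tg, tg) - eval_cov_surface(D2, tg, tg))^2
    w <- rep(c(2, 4), length.out = 401); w[c(1, 401)] <- 1
    oracle <- drop(w %*% f %*% w) * (h / 3)^2
    expect_equal(hs_distance(D1, D2), oracle, tolerance = 1e-6)
  }

  other <- build_basis(c(-1, 1), H = 8)
  expect_error(hs_distance(A, cov_surface(other, matrix(0, 8, 8))),
               class = "covgof_basis_error")
})

test_that("the bootstrap p-value is the strict exceedance fraction", {
  s <- simulate_dataset(sim_design(n = 30, m = 8, seed = 62))
  r <- run_gof_test(s, L = 9, seed = 63)
  expect_equal(r$p_value, mean(r$boot_stats > r$Tn))
  expect_true(all(r$boot_stats >= 0))
  expect_gte(r$Tn, 0)
  r1 <- run_gof_test(s, L = 1, seed = 64)
  expect_true(r1$p_value %in% c(0, 1))
})

test_that("bootstrap replicates are reproducible under their substream seed", {
  s <- simulate_dataset(sim_design(n = 30, m = 8, seed = 65))
  prep <- gof_prep(s)
  expect_identical(bootstrap_replicate(prep, 123L),
                   bootstrap_replicate(prep, 123L))
  expect_false(bootstrap_replicate(prep, 123L) ==
                 bootstrap_replicate(prep, 124L))

  r1 <- run_gof_test(s, L = 12, seed = 66)
  r2 <- run_gof_test(s, L = 12, seed = 66)
  expect_identical(r1$boot_stats, r2$boot_stats)
  expect_identical(r1$p_value, r2$p_value)
})

test_that("a degenerate null fit propagates to a near-zero replicate statistic", {
  set.seed(67)
  tt <- rep(seq(-1, 1, length.out = 8), 30)
  s <- fd_sample(rep(1:30, each = 8), tt, rep(0, 240), domain = c(-1, 1))
  # the identical-grid design is rank deficient for the smoother, which
  # exercises the minimum-norm fallback (warned about)
  prep <- suppressWarnings(gof_prep(s))
  expect_lt(prep$sigma2_alt, 1e-10)
  expect_lt(max(abs(prep$null_fit$V0)), 1e-6)
  expect_lt(bootstrap_replicate(prep, 68L), 1e-10)
})

test_that("the observed statistic is invariant to subject relabelling", {
  s <- simulate_dataset(sim_design(n = 40, m = 10, seed = 69))
  perm <- order(rev(seq_len(nrow(s$data))))
  s_perm <- fd_sample(paste0("z", s$data$subject[perm]), s$data$time[perm],
                      s$data$value[perm], domain = s$domain)
  expect_equal(gof_prep(s)$Tn, gof_prep(s_perm)$Tn, tolerance = 1e-6)
})

test_that("the squared-exponential null family runs through the same pipeline", {
  s <- simulate_dataset(sim_design(n = 40, m = 10, seed = 70))
  r <- run_gof_test(s, L = 8, seed = 71, family = "squared_exponential")
  expect_s3_class(r$null_fit, "null_cov_fit")
  expect_identical(r$null_fit$family, "squared_exponential")
  expect_true(is.finite(r$Tn) && r$Tn >= 0)
  expect_true(r$p_value >= 0 && r$p_value <= 1)
})
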