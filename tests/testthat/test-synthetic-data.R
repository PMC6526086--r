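test_that("dense designs observe every grid point; seeds reproduce exactly", {
  d <- sim_design(n = 5, m = 80, seed = 21)
  s <- simulate_dataset(d)
  grid <- seq(-1, 1, length.out = 80)
  for (id in unique(s$data$subject)) {
    expect_equal(s$data$time[s$data$subject == id], grid)
  }
  s2 <- simulate_dataset(sim_design(n = 5, m = 80, seed = 21))
  expect_identical(s$data, s2$data)

  # sparse designs: per-subject times are a without-replacement grid subset
  sp <- simulate_dataset(sim_design(n = 30, m = 12, seed = 22))
  for (id in unique(sp$data$subject)) {
    tt <- sp$data$time[sp$data$subject == id]
    expect_length(unique(tt), 12)
    expect_true(all(tt %in% grid))
  }
  expect_error(sim_design(n = 5, m = 81), class = "covgof_design_error")
})

test_that("null-generator moments match the quadratic polynomial covariance", {
  # Var{X(t)} = 1 - t + t^2 and Cov{X(t), X(t')} = G0(t,t') for delta = 0
  d <- sim_design(n = 4000, m = 80, noise_sd = 0, seed = 23)
  s <- simulate_dataset(d)
  X <- matrix(s$data$value, nrow = 80)  # common design: column per subject
  grid <- seq(-1, 1, length.out = 80)
  for (j in c(1, 20, 45, 80)) {
    expect_equal(var(X[j, ]), 1 - grid[j] + grid[j]^2, tolerance = 0.08)
  }
  expect_equal(cov(X[10, ], X[60, ]),
               1 - 0.5 * (grid[10] + grid[60]) + grid[10] * grid[60],
               tolerance = 0.12)
})

test_that("trigonometric deviation adds the rank-2 sine covariance", {
  delta <- 1.5
  d <- sim_design(n = 4000, m = 80, delta = delta,
                  deviation = "trigonometric", noise_sd = 0, seed = 24)
  s <- simulate_dataset(d)
  X <- matrix(s$data$value, nrow = 80)
  grid <- seq(-1, 1, length.out = 80)
  j <- 12; k <- 57
  expected <- 1 - 0.5 * (grid[j] + grid[k]) + grid[j] * grid[k] +
    delta^2 * (sin(2 * pi * grid[j]) * sin(2 * pi * grid[k]) +
                 sin(4 * pi * grid[j]) * sin(4 * pi * grid[k]))
  expect_equal(cov(X[j, ], X[k, ]), expected, tolerance = 0.15)
})

test_that("deviation size matches a dense trapezoid oracle and is monotone", {
  expect_identical(deviation_size(sim_design(10, 5, delta = 0)), 0)

  # quadratic deviation: integrand delta^2 t^4 / (1 - t + t^2 + delta^2 t^4)
  trapezoid_oracle <- function(delta) {
    t <- seq(-1, 1, length.out = 1e5)
    f <- delta^2 * t^4 / (1 - t + t^2 + delta^2 * t^4)
    sum((f[-1] + f[-length(f)]) / 2) * diff(t[1:2])
  }
  for (delta in c(0.3, 1, 2.7)) {
    got <- deviation_size(sim_design(10, 5, delta = delta,
                                     deviation = "quadratic"))
    expect_equal(got, trapezoid_oracle(delta), tolerance = 1e-8)
  }

  for (dev in c("quadratic", "trigonometric")) {
    grid_vals <- vapply(seq(0.1, 3, length.out = 12), function(dl) {
      deviation_size(sim_design(10, 5, delta = dl, deviation = dev))
    }, numeric(1))
    expect_true(all(diff(grid_vals) > 0))
  }
})
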