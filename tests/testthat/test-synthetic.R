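test_that("config validation enforces stability, symmetry and rates", {
  expect_error(synthetic_config(1, matrix(1.2), n_rows = 10), "stable")
  expect_silent(synthetic_config(1, matrix(1.2), n_rows = 10,
                                 allow_unstable = TRUE))
  s <- matrix(c(1, 0.5, 0.4, 1), 2)  # asymmetric
  expect_error(synthetic_config(2, diag(0.1, 2), sigma = s, n_rows = 5),
               "symmetric")
  expect_error(synthetic_config(1, matrix(0.5), n_rows = 5,
                                missing_rates = 1), "rates")
})

test_that("noise-free recursions follow their closed forms", {
  # B = 0, sigma = 0: every row after the first equals the intercept
  cfg <- synthetic_config(2, matrix(0, 2, 2), intercept = c(3, 7),
                          sigma = matrix(0, 2, 2), n_rows = 5,
                          positivity = "none")
  p <- simulate_var_panel(cfg)
  expect_equal(unname(unclass(p)[1, ]), c(0, 0))
  for (t in 2:5) expect_equal(unname(unclass(p)[t, ]), c(3, 7))

  # B = 0.5 I, sigma = 0, start displaced: geometric decay toward
  # intercept / (1 - 0.5)
  cfg2 <- synthetic_config(1, matrix(0.5), intercept = 1,
                           sigma = matrix(0), n_rows = 8,
                           baseline = 10, positivity = "none")
  p2 <- drop(unclass(simulate_var_panel(cfg2)))
  # deviations follow d_t = 1 + 0.5 d_{t-1}, d_0 = 0
  d <- 0
  for (t in 2:8) {
    d <- 1 + 0.5 * d
    expect_equal(p2[t], 10 + d)
  }
  expect_lt(abs(p2[8] - (10 + 2)), 1)  # approaching 1/(1-0.5) = 2
})

test_that("AR(1) simulation reproduces theoretical lag-1 autocorrelation", {
  cfg <- synthetic_config(1, matrix(0.7), sigma = matrix(1),
                          n_rows = 5000, seed = 99, positivity = "none")
  x <- drop(unclass(simulate_var_panel(cfg)))
  r <- cor(x[-1], x[-length(x)])
  expect_lt(abs(r - 0.7), 0.03)
})

test_that("stationary mean converges to (I - B)^-1 intercept plus baseline", {
  B <- matrix(c(0.5, 0.2, 0.1, 0.3), 2)
  cfg <- synthetic_config(2, B, intercept = c(1, 2), sigma = diag(2) * 0.25,
                          n_rows = 20000, baseline = c(5, 5), seed = 12,
                          positivity = "none")
  mu_theory <- 5 + solve(diag(2) - B, c(1, 2))
  mu_hat <- colMeans(unclass(simulate_var_panel(cfg)))
  expect_lt(max(abs(mu_hat - mu_theory)), 0.15)
})

test_that("regression of X_t on X_{t-1} recovers residual covariance", {
  B <- matrix(c(0.5, 0.1, 0.2, 0.4), 2)
  sigma <- matrix(c(1, 0.3, 0.3, 0.5), 2)
  cfg <- synthetic_config(2, B, sigma = sigma, n_rows = 20000, seed = 77,
                          positivity = "none")
  fit <- var_fit(simulate_var_panel(cfg), p = 1)
  expect_lt(max(abs(fit$sigma_hat - sigma)), 0.06)
})

test_that("missingness is MCAR, rate-faithful and never total", {
  m <- matrix(rnorm(3000), 1000, 3, dimnames = list(NULL, c("a", "b", "c")))
  p <- make_panel(m)
  expect_identical(unclass(apply_missingness(p, 0, seed = 1)), unclass(p))

  p2 <- apply_missingness(p, 0.5, seed = 8)
  obs <- observation_counts(p2)$observed
  expect_true(all(abs(obs - 500) <= 50))  # binomial 3 sigma
  # observed cells keep exact values
  keep <- !is.na(unclass(p2))
  expect_identical(unclass(p2)[keep], unclass(p)[keep])
  # MCAR: observed-cell means agree with full-column means
  expect_lt(max(abs(colMeans(unclass(p2), na.rm = TRUE) - colMeans(m))),
            4 * max(apply(m, 2, sd)) / sqrt(400))

  p3 <- apply_missingness(make_panel(m[1:10, ]), 0.99, seed = 3)
  expect_true(all(observation_counts(p3)$observed >= 1))
  expect_error(apply_missingness(p, 1), "rates")
})

test_that("benchmark case is deterministic and encodes the dependence chain", {
  b1 <- make_benchmark_case(seed = 21)
  b2 <- make_benchmark_case(seed = 21)
  expect_identical(unclass(b1$panel), unclass(b2$panel))
  B <- b1$config$B
  expect_gt(B["AP", "CRP"], 0)
  expect_gt(B["proteinuria", "AP"], 0)
  expect_equal(B["proteinuria", "CRP"], 0)
  expect_equal(unname(B["NTproBNP", c("CRP", "AP", "proteinuria")]),
               c(0, 0, 0))
  expect_equal(nrow(b1$panel), 208L)
  expect_equal(panel_step(b1$panel), 6)
  # expected observed count for the sparsest marker
  expect_equal(round((1 - b1$config$missing_rates[4]) * 208), 22)
})
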