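test_that("diagonal VAR(1) has the geometric closed-form IRF", {
  fit <- list(B = list(diag(0.5, 2)), sigma_hat = diag(2),
              var_names = c("a", "b"))
  ir <- compute_irf(fit, "a", H = 6, impulse_scale = "unit")
  expect_equal(unname(ir$responses[, "a"]), 0.5^(0:6))
  expect_equal(unname(ir$responses[, "b"]), rep(0, 7))
})

test_that("published coefficient matrix gives the anchored responses", {
  B <- amyloid_case_coefficients()
  fit <- list(B = list(B), sigma_hat = NULL, var_names = rownames(B))
  ir <- compute_irf(fit, "CRP", H = 8, impulse_scale = "unit")
  expect_equal(unname(ir$responses[2, "AP"]), 1.40)
  expect_equal(unname(ir$responses[3, "AP"]), 0.46 * 1.40 + 1.40 * 0.70)
  # all horizons equal the matrix-power oracle
  for (h in 0:8) {
    expect_equal(unname(ir$responses[h + 1, ]),
                 unname(mat_pow(B, h)[, "CRP"]),
                 tolerance = 1e-12)
  }
})

test_that("non-orthogonalized IRF equals the two-path simulation oracle", {
  set.seed(17)
  for (case in 1:20) {
    K <- sample(2:3, 1)
    p <- sample(1:2, 1)
    x <- oracle_sim_var(replicate(p, random_stable_B(K, 0.4 / p),
                                  simplify = FALSE), diag(K), 80,
                        seed = 400 + case)
    fit <- var_fit(make_panel(x), p = p)
    j <- sample(K, 1)
    ir <- compute_irf(fit, fit$var_names[j], H = 10)
    v <- numeric(K)
    v[j] <- sqrt(fit$sigma_hat[j, j])
    expect_lt(max(abs(ir$responses - oracle_irf_two_path(fit$B, v, 10))),
              1e-10)
  }
})

test_that("orthogonalization reconstructs sigma and reduces to sd-scaling when diagonal", {
  bench <- make_benchmark_case(seed = 6, missing = FALSE)
  fit <- var_fit(bench$complete)
  P <- t(chol(fit$sigma_hat))
  expect_lt(max(abs(P %*% t(P) - fit$sigma_hat)), 1e-10)

  # diagonal sigma: orthogonalized equals sd-scaled non-orthogonalized
  fit2 <- list(B = list(diag(c(0.4, 0.6))), sigma_hat = diag(c(4, 9)),
               var_names = c("a", "b"))
  expect_equal(compute_irf(fit2, "b", H = 5, ortho = TRUE)$responses,
               compute_irf(fit2, "b", H = 5)$responses)
})

test_that("reordering changes orthogonalized but not plain IRFs", {
  bench <- make_benchmark_case(seed = 8, missing = FALSE)
  fit <- var_fit(bench$complete)
  ord1 <- fit$var_names
  ord2 <- rev(ord1)
  plain1 <- compute_irf(fit, "CRP", H = 6)
  plain2 <- compute_irf(fit, "CRP", H = 6, order = ord2)
  expect_equal(plain1$responses, plain2$responses)
  o1 <- compute_irf(fit, "CRP", H = 6, ortho = TRUE, order = ord1)
  o2 <- compute_irf(fit, "CRP", H = 6, ortho = TRUE, order = ord2)
  expect_gt(max(abs(o1$responses - o2$responses)), 1e-8)
})

test_that("bands collapse onto the point IRF for a deterministic series", {
  cfg <- synthetic_config(2, diag(c(0.5, 0.8)), sigma = matrix(0, 2, 2),
                          intercept = c(1, 1), n_rows = 40,
                          baseline = c(20, 20), positivity = "none",
                          var_names = c("a", "b"))
  panel <- simulate_var_panel(cfg)
  ir <- irf_bands(panel, impulse = "a", H = 6, n_boot = 100, seed = 1,
                  impulse_scale = "unit")
  expect_equal(ir$lower, ir$responses, tolerance = 1e-8)
  expect_equal(ir$upper, ir$responses, tolerance = 1e-8)
})

test_that("bands contain the point response and are seed-reproducible", {
  bench <- make_benchmark_case(seed = 10, missing = FALSE)
  ir1 <- irf_bands(bench$complete, impulse = "CRP", H = 8, n_boot = 100,
                   seed = 5)
  ir2 <- irf_bands(bench$complete, impulse = "CRP", H = 8, n_boot = 100,
                   seed = 5)
  expect_identical(ir1$lower, ir2$lower)
  expect_identical(ir1$upper, ir2$upper)
  expect_true(all(ir1$lower <= ir1$upper))
})

test_that("bands widen on shorter samples of the same process", {
  width <- sapply(c(208L, 60L), function(n) {
    w <- sapply(1:5, function(s) {
      cfg <- make_benchmark_case(seed = s, missing = FALSE)$config
      cfg2 <- synthetic_config(4, cfg$B, sigma = cfg$sigma, n_rows = n,
                               baseline = cfg$baseline, seed = s,
                               var_names = cfg$var_names)
      ir <- irf_bands(simulate_var_panel(cfg2), impulse = "CRP", H = 6,
                      n_boot = 100, seed = s)
      mean(ir$upper[, "AP"] - ir$lower[, "AP"])
    })
    mean(w)
  })
  expect_gt(width[2], width[1])
})

test_that("return-to-baseline follows the all-later-horizons rule", {
  mk <- function(lower, upper) {
    structure(list(responses = cbind(x = (lower + upper) / 2),
                   lower = cbind(x = lower), upper = cbind(x = upper),
                   horizons = 0:(length(lower) - 1), var_names = "x",
                   impulse = "x"),
              class = "varirf")
  }
  # zero excluded at h = 0, 1 only
  expect_equal(return_to_baseline(mk(c(1, 1, -1, -1), c(2, 2, 1, 1)), "x"), 2)
  # always included
  expect_equal(return_to_baseline(mk(rep(-1, 4), rep(1, 4)), "x"), 0)
  # oscillating: excluded at h = 3 only, so the answer is 4 not 1
  expect_equal(return_to_baseline(
    mk(c(-1, -1, -1, 1, -1), c(1, 1, 1, 2, 1)), "x"), 4)
  # excluded at the final horizon: never returns within H
  expect_equal(return_to_baseline(mk(c(-1, 1), c(1, 2)), "x"), Inf)
  expect_error(return_to_baseline(mk(0, 1), "nope"), "unknown")
})
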