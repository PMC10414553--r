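test_that("a hand-solvable AR(1) is fitted exactly", {
  # alternating series: 4 lag pairs (1,2),(2,1),(1,2),(2,1)
  # normal equations give slope -1, intercept 3, zero residuals
  p <- make_panel(matrix(c(1, 2, 1, 2, 1), ncol = 1,
                         dimnames = list(NULL, "x")))
  fit <- var_fit(p, p = 1)
  expect_equal(unname(fit$B[[1]][1, 1]), -1)
  expect_equal(unname(fit$A[1, "const"]), 3)
  expect_equal(max(abs(fit$residuals)), 0)
  expect_equal(fit$n_eff, 4L)
})

test_that("estimates agree with the brute-force normal-equations oracle", {
  set.seed(101)
  for (case in 1:60) {
    K <- sample(1:3, 1)
    p <- sample(1:2, 1)
    n <- sample(20:50, 1)
    x <- oracle_sim_var(replicate(p, random_stable_B(K, 0.4 / p),
                                  simplify = FALSE),
                        diag(K), n, seed = 101 + case)
    exog <- if (runif(1) < 0.3) matrix(rnorm(n), n, 1,
                                       dimnames = list(NULL, "z1"))
    fit <- var_fit(make_panel(x), p = p, exog = exog)
    orc <- oracle_var_ols(x, p, exog)
    # package layout: row = equation; oracle layout: column = equation,
    # rows ordered const, lag blocks, exog
    ours <- cbind(fit$A[, "const"], do.call(cbind, fit$B),
                  if (!is.null(exog)) fit$A[, -1])
    expect_lt(max(abs(ours - t(orc$coef))), 1e-8)
    # fitted + residuals reconstruct the dependent rows
    expect_lt(max(abs(fit$fitted + fit$residuals - fit$y)), 1e-8)
  }
})

test_that("white noise yields near-zero coefficient estimates", {
  set.seed(55)
  x <- matrix(rnorm(2000 * 2), 2000, 2, dimnames = list(NULL, c("a", "b")))
  fit <- var_fit(make_panel(x), p = 1)
  expect_lt(max(abs(fit$B[[1]])), 0.1)
})

test_that("missing cells and singular designs raise instructive errors", {
  m <- matrix(rnorm(40), 20, 2, dimnames = list(NULL, c("a", "b")))
  m[3, 1] <- NA
  expect_error(var_fit(make_panel(m)), "impute")
  m[3, 1] <- 0
  dup <- cbind(m, c = m[, 2])  # c duplicates b
  expect_error(var_fit(make_panel(dup)), "collinear")
})

test_that("information criteria follow their closed-form definitions", {
  set.seed(7)
  x <- matrix(rnorm(103), ncol = 1, dimnames = list(NULL, "x"))
  fit <- var_fit(make_panel(x), p = 1, n_presample = 3)  # n_eff = 100
  ld <- log(sum(fit$residuals^2) / 100)
  expect_equal(fit$aic, ld + (2 / 100) * 2)
  expect_equal(fit$sbic, ld + (log(100) / 100) * 2)
  expect_equal(fit$hqic, ld + (2 * log(log(100)) / 100) * 2)
  expect_equal(unname(information_criteria(fit)["aic"]), fit$aic)
})

test_that("residual determinant is non-increasing in lag order on a common sample", {
  set.seed(13)
  x <- oracle_sim_var(random_stable_B(2), diag(2), 120, seed = 13)
  sel <- select_lag_order(make_panel(x), p_max = 4)
  dets <- sel$aic - (2 / sel$n_eff) * 2 * (2 * sel$p + 1)  # log det term
  expect_true(all(diff(dets) <= 1e-10))
  expect_equal(sel$n_eff, rep(116, 4))  # identical estimation rows
  expect_true(all(attr(sel, "selected") >= 1))
})

test_that("lag selection with p_max = 1 is trivial", {
  x <- oracle_sim_var(matrix(0.5), matrix(1), 40, seed = 2)
  sel <- select_lag_order(make_panel(x), p_max = 1)
  expect_true(all(attr(sel, "selected") == 1))
})

test_that("companion-matrix stability matches hand eigenvalues", {
  expect_true(check_stability(matrix(0, 3, 3))$stable)
  expect_equal(check_stability(matrix(0, 3, 3))$moduli, rep(0, 3))
  st <- check_stability(diag(2))
  expect_false(st$stable)
  expect_equal(st$moduli, c(1, 1))
  # 2x2: eigenvalues (tr +- sqrt(tr^2 - 4 det)) / 2
  B <- matrix(c(0.5, 0.1, 0.2, 0.3), 2)
  st2 <- check_stability(B)
  expect_equal(st2$moduli[1], (0.8 + sqrt(0.8^2 - 4 * 0.13)) / 2)
  expect_equal(round(st2$moduli[1], 4), 0.5732)
  expect_true(st2$stable)
  # VAR(2) companion stacks an identity block
  cm <- companion_matrix(list(diag(0.5, 2), diag(0.25, 2)))
  expect_equal(dim(cm), c(4L, 4L))
  expect_equal(cm[3:4, 1:2], diag(2))
})

test_that("one-step forecasts are linear with published-matrix gains", {
  B <- amyloid_case_coefficients()
  unit <- function(v) {
    s <- setNames(rep(0, 4), colnames(B))
    s[v] <- 1
    s
  }
  expect_equal(unname(var_forecast(B, state = unit("CRP"))["AP"]), 1.40)
  expect_equal(unname(var_forecast(B, state = unit("AP"))["proteinuria"]),
               31.76)
  expect_equal(unname(var_forecast(B, state = unit("CRP"))["CRP"]), 0.70)

  # B = 0 with exogenous constants: prediction is the constant
  A <- matrix(c(2, 5), 2, 1)
  expect_equal(unname(var_forecast(matrix(0, 2, 2), A,
                                   state = c(9, 9), z = 1)), c(2, 5))
  # B = I: prediction equals the previous state
  expect_equal(unname(var_forecast(diag(3), state = c(1, 2, 3))),
               c(1, 2, 3))
  # linearity in the state when there is no exogenous part
  set.seed(3)
  Br <- random_stable_B(3)
  s1 <- rnorm(3); s2 <- rnorm(3)
  expect_equal(var_forecast(Br, state = 2 * s1 + 3 * s2),
               2 * var_forecast(Br, state = s1) +
                 3 * var_forecast(Br, state = s2))
})

test_that("predict() iterates the fitted recursion", {
  bench <- make_benchmark_case(seed = 2, missing = FALSE)
  fit <- var_fit(bench$complete, p = 1)
  one <- predict(fit)
  n <- nrow(fit$y)
  by_hand <- drop(fit$B[[1]] %*% fit$y[n, ]) + fit$A[, "const"]
  expect_equal(unname(one), unname(by_hand))
  two <- predict(fit, n_ahead = 2)
  expect_equal(unname(two[2, ]),
               unname(drop(fit$B[[1]] %*% two[1, ]) + fit$A[, "const"]))
})

test_that("Rubin pooling reproduces hand arithmetic", {
  fake_fit <- function(est, se) {
    structure(list(coef_matrix = matrix(est, 1, 1,
                                        dimnames = list("x", "x.l1")),
                   se_matrix = matrix(se, 1, 1),
                   p = 1L, K = 1L, m = 0L, n_eff = 50L, df_resid = 48L,
                   var_names = "x", exog_names = character(0)),
              class = "varfit")
  }
  pool <- pool_rubin(list(fake_fit(1, sqrt(0.5)), fake_fit(2, sqrt(0.5))))
  expect_equal(unname(pool$est[1, 1]), 1.5)
  expect_equal(unname(pool$W[1, 1]), 0.5)
  expect_equal(unname(pool$between[1, 1]), 0.5)
  expect_equal(unname(pool$total[1, 1]), 0.5 + 1.5 * 0.5)
  expect_equal(unname(pool$se[1, 1]), sqrt(1.25))
  # Rubin df: (M-1) (1 + W / ((1+1/M) B))^2
  expect_equal(unname(pool$df[1, 1]), (1 + 0.5 / 0.75)^2)

  # M = 1: pooled equals the single fit with zero between-variance
  single <- pool_rubin(list(fake_fit(1.7, 0.3)))
  expect_equal(unname(single$est[1, 1]), 1.7)
  expect_equal(unname(single$se[1, 1]), 0.3)
  expect_equal(unname(single$between[1, 1]), 0)
  expect_equal(unname(single$df[1, 1]), 48)

  # identical fits: between-variance 0, pooled se = single-fit se
  rep3 <- pool_rubin(replicate(3, fake_fit(0.9, 0.2), simplify = FALSE))
  expect_equal(unname(rep3$between[1, 1]), 0)
  expect_equal(unname(rep3$se[1, 1]), 0.2)
  expect_equal(unname(rep3$df[1, 1]), Inf)

  expect_error(pool_rubin(list(fake_fit(1, 1),
                               structure(list(p = 2L), class = "varfit"))),
               "specification")
})

test_that("t-values equal coefficient over standard error where defined", {
  bench <- make_benchmark_case(seed = 4, missing = FALSE)
  fit <- var_fit(bench$complete)
  expect_equal(fit$t_matrix, fit$coef_matrix / fit$se_matrix)
  expect_lt(max(abs(fit$sigma_hat - t(fit$sigma_hat))), 1e-10)
})
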