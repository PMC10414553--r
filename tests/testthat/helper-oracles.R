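# Independent oracles used across the suite. These deliberately avoid the
# package's own linear-algebra paths: plain normal equations, explicit
# recursions, rank-then-Pearson.

# per-equation OLS via explicit normal equations on a hand-built design
oracle_var_ols <- function(x, p, exog = NULL) {
  n <- nrow(x)
  K <- ncol(x)
  rows <- (p + 1):n
  X <- matrix(1, length(rows), 1)
  for (l in 1:p) X <- cbind(X, x[rows - l, , drop = FALSE])
  if (!is.null(exog)) X <- cbind(X, exog[rows, , drop = FALSE])
  coef <- solve(t(X) %*% X, t(X) %*% x[rows, , drop = FALSE])
  list(coef = coef, design = X, y = x[rows, , drop = FALSE])
}

# non-orthogonalized IRF by two-path simulation: run the deterministic
# recursion with and without the impulse added to the error at time 0
oracle_irf_two_path <- function(B, v, H) {
  if (is.matrix(B)) B <- list(B)
  p <- length(B)
  K <- nrow(B[[1]])
  x1 <- matrix(0, H + 1 + p, K)
  x2 <- matrix(0, H + 1 + p, K)
  x1[p + 1, ] <- v
  if (H >= 1) {
    for (t in (p + 2):(H + 1 + p)) {
      for (l in 1:p) {
        x1[t, ] <- x1[t, ] + drop(B[[l]] %*% x1[t - l, ])
        x2[t, ] <- x2[t, ] + drop(B[[l]] %*% x2[t - l, ])
      }
    }
  }
  x1[(p + 1):(p + 1 + H), , drop = FALSE] -
    x2[(p + 1):(p + 1 + H), , drop = FALSE]
}

# simulate a VAR(p) with Gaussian errors, zero mean, explicit loop
oracle_sim_var <- function(B, sigma, n, burn = 50, seed = NULL) {
  if (is.matrix(B)) B <- list(B)
  if (!is.null(seed)) set.seed(seed)
  p <- length(B)
  K <- nrow(B[[1]])
  ch <- chol(sigma)
  total <- n + burn + p
  x <- matrix(0, total, K)
  e <- matrix(rnorm(total * K), total, K) %*% ch
  for (t in (p + 1):total) {
    x[t, ] <- e[t, ]
    for (l in 1:p) x[t, ] <- x[t, ] + drop(B[[l]] %*% x[t - l, ])
  }
  out <- x[(burn + p + 1):total, , drop = FALSE]
  colnames(out) <- paste0("V", 1:K)
  out
}

# random stable VAR(1) coefficient matrix (rescaled to spectral radius rho)
random_stable_B <- function(K, rho = 0.6) {
  B <- matrix(rnorm(K * K, sd = 0.5), K, K)
  sr <- max(Mod(eigen(B, only.values = TRUE)$values))
  if (sr > 0) B <- B * (rho / sr)
  B
}

mat_pow <- function(M, h) {
  out <- diag(nrow(M))
  dimnames(out) <- dimnames(M)
  while (h > 0) {
    out <- out %*% M
    h <- h - 1
  }
  out
}

# Spearman's rho by explicit rank-then-Pearson arithmetic
oracle_spearman <- function(x, y) {
  rx <- rank(x)
  ry <- rank(y)
  mx <- mean(rx)
  my <- mean(ry)
  sum((rx - mx) * (ry - my)) /
    sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
}

make_panel <- function(m, step = 6) regular_panel(m, step = step)
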