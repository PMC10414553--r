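#' Fit a vector autoregression by per-equation least squares
#'
#' Estimates the model `X_t = B_1 X_{t-1} + ... + B_p X_{t-p} + A Z_t + u_t`
#' on a complete regular panel. Each of the K equations is estimated by
#' ordinary least squares of `x_{i,t}` on the p lagged state vectors and the
#' exogenous row `Z_t` (which always contains the regression constant);
#' this equals the closed-form normal-equations solution.
#'
#' @param panel a complete [regular_panel] (no missing cells; impute first,
#'   e.g. with [impute_chained()]), or a plain numeric matrix.
#' @param p lag order (>= 1).
#' @param exog optional T x m2 matrix/data.frame of exogenous covariates;
#'   the constant is always added internally and must not be supplied.
#' @param n_presample number of initial rows reserved as presample (defaults
#'   to `p`; [select_lag_order()] sets it to `p_max` so that candidate fits
#'   share the same estimation rows).
#'
#' @return An object of class `varfit` with components
#' \describe{
#'   \item{B}{list of p K x K lag-coefficient matrices; entry `[i, j]` of
#'     `B[[l]]` is the effect of variable j at lag l on variable i now.}
#'   \item{A}{K x m exogenous coefficient matrix; column `const` holds the
#'     intercepts.}
#'   \item{se_B, se_A, t_B, t_A}{standard errors and t-values, same shapes.}
#'   \item{sigma_hat}{residual covariance, divisor `n_eff - (K p + m)`.}
#'   \item{sigma_ml}{maximum-likelihood residual covariance, divisor `n_eff`.}
#'   \item{residuals, fitted}{`(T - n_presample)` x K matrices.}
#'   \item{aic, sbic, hqic, loglik}{information criteria / Gaussian
#'     log-likelihood (see [information_criteria()]).}
#' }
#' Standard methods are available: `print`, `summary` (coefficient table
#' with t-values and significance stars), `coef`, `predict` (one-step and
#' iterated forecasts), `residuals`, `fitted`, `logLik`, `simulate`.
#'
#' @examples
#' bench <- make_benchmark_case(seed = 1, missing = FALSE)
#' fit <- var_fit(bench$complete, p = 1)
#' coef(fit)["AP", "CRP.l1"]
#' @export
var_fit <- function(panel, p = 1, exog = NULL, n_presample = p) {
  x <- if (inherits(panel, "regular_panel")) panel_matrix(panel)
       else as.matrix(panel)
  if (anyNA(x))
    stop("panel has missing cells; impute first (see impute_chained)")
  if (p < 1) stop("lag order p must be >= 1")
  if (n_presample < p) stop("n_presample must be >= p")
  n_rows <- nrow(x)
  K <- ncol(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(K))
  vars <- colnames(x)
  Z <- build_exog(exog, n_rows)
  m <- ncol(Z)
  rows <- (n_presample + 1L):n_rows
  n_eff <- length(rows)
  q <- K * p + m
  if (n_eff - q < 1L)
    stop("not enough rows: need T - n_presample > K*p + m")
  Y <- x[rows, , drop = FALSE]
  D <- matrix(NA_real_, n_eff, q)
  cn <- character(q)
  for (l in seq_len(p)) {
    D[, (l - 1L) * K + seq_len(K)] <- x[rows - l, , drop = FALSE]
    cn[(l - 1L) * K + seq_len(K)] <- paste0(vars, ".l", l)
  }
  D[, K * p + seq_len(m)] <- Z[rows, , drop = FALSE]
  cn[K * p + seq_len(m)] <- colnames(Z)
  colnames(D) <- cn
  qr_d <- qr(D)
  if (qr_d$rank < q) {
    bad <- colnames(D)[qr_d$pivot[-seq_len(qr_d$rank)]]
    stop("singular design matrix; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  C <- qr.coef(qr_d, Y)                      # q x K
  fitted_vals <- D %*% C
  res <- Y - fitted_vals
  df_resid <- n_eff - q
  sigma_hat <- crossprod(res) / df_resid
  sigma_ml <- crossprod(res) / n_eff
  XtX_inv <- chol2inv(qr.R(qr_d))[order(qr_d$pivot), order(qr_d$pivot)]
  se <- sqrt(outer(diag(XtX_inv), diag(sigma_hat)))  # q x K
  dimnames(se) <- dimnames(C)
  tval <- ifelse(se > 0, C / se, NA_real_)
  coefs <- t(C)                              # K x q, row = equation
  se_t <- t(se); tval_t <- t(tval)
  B <- se_B <- t_B <- vector("list", p)
  for (l in seq_len(p)) {
    idx <- (l - 1L) * K + seq_len(K)
    B[[l]] <- coefs[, idx, drop = FALSE]
    se_B[[l]] <- se_t[, idx, drop = FALSE]
    t_B[[l]] <- tval_t[, idx, drop = FALSE]
    colnames(B[[l]]) <- colnames(se_B[[l]]) <- colnames(t_B[[l]]) <- vars
  }
  eidx <- K * p + seq_len(m)
  A <- coefs[, eidx, drop = FALSE]
  ld <- log_det_psd(sigma_ml)
  loglik <- -(n_eff / 2) * (K * log(2 * pi) + ld + K)
  crit <- function(pen) ld + (pen / n_eff) * K * q
  fit <- structure(list(
    B = B, A = A,
    se_B = se_B, se_A = se_t[, eidx, drop = FALSE],
    t_B = t_B, t_A = tval_t[, eidx, drop = FALSE],
    residuals = res, fitted = fitted_vals, y = Y,
    sigma_hat = sigma_hat, sigma_ml = sigma_ml,
    n_eff = n_eff, df_resid = df_resid, p = p, K = K, m = m,
    var_names = vars, exog_names = colnames(Z),
    coef_matrix = coefs, se_matrix = se_t, t_matrix = tval_t,
    loglik = loglik,
    aic = crit(2), sbic = crit(log(n_eff)),
    hqic = crit(2 * log(log(n_eff))),
    exog = Z, presample = x[seq_len(n_presample), , drop = FALSE],
    n_presample = n_presample,
    step = if (inherits(panel, "regular_panel")) panel_step(panel) else NA,
    call = match.call()),
    class = "varfit")
  fit
}

# intercept-first exogenous design; `exog` holds additional columns only
build_exog <- function(exog, n_rows) {
  if (is.null(exog)) {
    Z <- matrix(1, n_rows, 1L, dimnames = list(NULL, "const"))
    return(Z)
  }
  Z2 <- as.matrix(exog)
  storage.mode(Z2) <- "double"
  if (ncol(Z2) == 0L)
    return(matrix(1, n_rows, 1L, dimnames = list(NULL, "const")))
  if (nrow(Z2) != n_rows)
    stop("exog must have one row per panel row (", n_rows, ")")
  if (anyNA(Z2)) stop("exogenous design must not contain missing cells")
  if (is.null(colnames(Z2))) colnames(Z2) <- paste0("z", seq_len(ncol(Z2)))
  if ("const" %in% colnames(Z2))
    stop("do not supply a 'const' column; the intercept is added internally")
  cbind(matrix(1, n_rows, 1L, dimnames = list(NULL, "const")), Z2)
}

log_det_psd <- function(sigma) {
  d <- determinant(sigma, logarithm = TRUE)
  if (d$sign <= 0) -Inf else as.numeric(d$modulus)
}

#' Exogenous design helpers
#'
#' `make_pulse_indicator()` expands a set of event days (e.g. drug
#' administrations) into a per-row 0/1 indicator that is 1 in each grid bin
#' containing at least one event. `make_gap_covariate()` returns, per grid
#' row, the number of days since the most recent row with at least one
#' observed endogenous cell (0 for the first row), a proxy for irregular
#' measurement spacing.
#'
#' @param panel a [regular_panel].
#' @param event_days numeric vector of event days.
#' @return A length-T numeric vector.
#' @export
make_pulse_indicator <- function(panel, event_days) {
  days <- panel_days(panel)
  step <- panel_step(panel)
  out <- numeric(nrow(panel))
  bin <- floor((event_days - attr(panel, "t0")) / step) + 1L
  bin <- bin[bin >= 1L & bin <= nrow(panel)]
  out[bin] <- 1
  out
}

#' @rdname make_pulse_indicator
#' @export
make_gap_covariate <- function(panel) {
  m <- panel_matrix(panel)
  days <- panel_days(panel)
  has_obs <- rowSums(!is.na(m)) > 0L
  gap <- numeric(nrow(m))
  last_day <- days[1L]
  for (i in seq_len(nrow(m))) {
    gap[i] <- days[i] - last_day
    if (has_obs[i]) last_day <- days[i]
  }
  gap
}

#' Information criteria of a VAR fit
#'
#' `aic = log det(Sigma_ml) + (2 / n_eff) * K * (K p + m)`; SBIC replaces the
#' 2 by `log(n_eff)`, HQIC by `2 log(log(n_eff))`. `Sigma_ml` is the
#' maximum-likelihood residual covariance (divisor `n_eff`).
#'
#' @param fit a [var_fit()] result.
#' @return Named numeric vector `c(aic, sbic, hqic)`.
#' @export
information_criteria <- function(fit) {
  stopifnot(inherits(fit, "varfit"))
  out <- c(aic = fit$aic, sbic = fit$sbic, hqic = fit$hqic)
  if (any(!is.finite(out)))
    stop("degenerate fit: residual covariance is singular")
  out
}

#' Companion-form stability check
#'
#' Assembles the `Kp x Kp` companion matrix of the lag coefficients and
#' reports its eigenvalue moduli; the VAR is stable (stationary) iff all
#' moduli are below 1.
#'
#' @param x a [var_fit()] result, a single K x K lag-1 matrix, or a list of
#'   p K x K matrices.
#' @return A list with `moduli` (sorted decreasing) and `stable` (logical).
#' @examples
#' check_stability(matrix(c(0.5, 0.1, 0.2, 0.3), 2))$stable
#' @export
check_stability <- function(x) {
  B <- if (inherits(x, "varfit")) x$B
       else if (is.matrix(x)) list(x)
       else x
  cm <- companion_matrix(B)
  moduli <- sort(Mod(eigen(cm, only.values = TRUE)$values),
                 decreasing = TRUE)
  list(moduli = moduli, stable = all(moduli < 1))
}

#' @rdname check_stability
#' @param B list of p K x K lag-coefficient matrices.
#' @export
companion_matrix <- function(B) {
  if (is.matrix(B)) B <- list(B)
  p <- length(B)
  K <- nrow(B[[1L]])
  cm <- matrix(0, K * p, K * p)
  for (l in seq_len(p))
    cm[seq_len(K), (l - 1L) * K + seq_len(K)] <- B[[l]]
  if (p > 1L)
    cm[K + seq_len(K * (p - 1L)), seq_len(K * (p - 1L))] <-
      diag(K * (p - 1L))
  cm
}

#' Lag-order selection by information criteria
#'
#' Fits VAR(p) for `p = 1, ..., p_max` on a common estimation sample (the
#' first `p_max` rows are dropped for every candidate, so the criteria are
#' computed on identical data) and reports the per-criterion argmin.
#'
#' @param panel complete [regular_panel].
#' @param p_max largest candidate lag order.
#' @param exog optional exogenous covariates as in [var_fit()].
#' @return A `lag_selection` object: data.frame of criteria by `p`, with
#'   attributes `selected` (named vector of argmins per criterion) and
#'   `agreement` (do all criteria pick the same p?).
#' @export
select_lag_order <- function(panel, p_max, exog = NULL) {
  if (p_max < 1) stop("p_max must be >= 1")
  fits <- lapply(seq_len(p_max), function(p)
    var_fit(panel, p = p, exog = exog, n_presample = p_max))
  tab <- data.frame(
    p = seq_len(p_max),
    aic = vapply(fits, `[[`, numeric(1), "aic"),
    sbic = vapply(fits, `[[`, numeric(1), "sbic"),
    hqic = vapply(fits, `[[`, numeric(1), "hqic"),
    loglik = vapply(fits, `[[`, numeric(1), "loglik"),
    n_eff = vapply(fits, `[[`, numeric(1), "n_eff"))
  selected <- c(aic = tab$p[which.min(tab$aic)],
                sbic = tab$p[which.min(tab$sbic)],
                hqic = tab$p[which.min(tab$hqic)])
  structure(tab, selected = selected,
            agreement = length(unique(selected)) == 1L,
            class = c("lag_selection", "data.frame"))
}

#' @export
print.lag_selection <- function(x, ...) {
  cat("Lag-order selection (common estimation sample)\n")
  print.data.frame(x, row.names = FALSE, digits = 5)
  sel <- attr(x, "selected")
  cat("Selected p:", paste(names(sel), sel, sep = " = ", collapse = ", "),
      "\n")
  if (!attr(x, "agreement"))
    cat("Note: the criteria disagree on the lag order.\n")
  invisible(x)
}

#' One-step forecast from fixed VAR coefficients
#'
#' Computes `sum_l B_l X_{t-l} + A Z_t` from explicitly supplied coefficient
#' matrices -- e.g. a published coefficient table -- without needing a
#' fitted object. The forecast is linear in the state, so raising the lag-1
#' component of variable j by one unit raises the prediction by column j of
#' `B_1`.
#'
#' @param B a K x K lag-1 matrix or list of p K x K matrices (entry
#'   `[i, j]` = effect of lagged variable j on variable i).
#' @param A optional K x m exogenous coefficient matrix.
#' @param state numeric state: a length-K vector (p = 1) or a p x K matrix
#'   whose rows are ordered oldest to newest (last row = lag 1).
#' @param z optional length-m exogenous row matching `A`.
#' @return Named length-K prediction.
#' @examples
#' B <- matrix(c(0.5, 0, 0, 0.5), 2)
#' var_forecast(B, state = c(1, 2))
#' @export
var_forecast <- function(B, A = NULL, state, z = NULL) {
  if (is.matrix(B)) B <- list(B)
  p <- length(B)
  K <- nrow(B[[1L]])
  state <- if (is.matrix(state)) state else matrix(state, nrow = 1L)
  if (nrow(state) != p || ncol(state) != K)
    stop("state must be a ", p, " x ", K, " matrix (rows oldest to newest)")
  pred <- numeric(K)
  for (l in seq_len(p))
    pred <- pred + drop(B[[l]] %*% state[p + 1L - l, ])
  if (!is.null(A)) {
    A <- as.matrix(A)
    if (is.null(z)) stop("z required when A is supplied")
    if (length(z) != ncol(A)) stop("length(z) must equal ncol(A)")
    pred <- pred + drop(A %*% z)
  }
  names(pred) <- rownames(B[[1L]])
  pred
}

#' @export
predict.varfit <- function(object, state = NULL, z = NULL, n_ahead = 1, ...) {
  p <- object$p
  K <- object$K
  if (is.null(state)) {
    n <- nrow(object$y)
    state <- object$y[(n - p + 1L):n, , drop = FALSE]
  }
  state <- if (is.matrix(state)) state else matrix(state, nrow = p)
  if (is.null(z)) z <- c(1, rep(0, object$m - 1L))
  out <- matrix(NA_real_, n_ahead, K,
                dimnames = list(NULL, object$var_names))
  for (h in seq_len(n_ahead)) {
    pred <- var_forecast(object$B, object$A, state, z)
    out[h, ] <- pred
    state <- rbind(state[-1L, , drop = FALSE], pred)
  }
  if (n_ahead == 1L) drop(out) else out
}

#' @export
residuals.varfit <- function(object, ...) object$residuals

#' @export
fitted.varfit <- function(object, ...) object$fitted

#' @export
logLik.varfit <- function(object, ...) {
  structure(object$loglik, df = object$K * (object$K * object$p + object$m),
            nobs = object$n_eff, class = "logLik")
}

#' @export
coef.varfit <- function(object, ...) object$coef_matrix

#' @export
print.varfit <- function(x, ...) {
  cat(sprintf("VAR(%d) fit: K = %d variables, n_eff = %d, m = %d exogenous\n",
              x$p, x$K, x$n_eff, x$m))
  st <- check_stability(x)
  cat(sprintf("Stable: %s (max eigenvalue modulus %.3f)\n",
              st$stable, st$moduli[1L]))
  cat(sprintf("AIC %.4f  SBIC %.4f  HQIC %.4f\n", x$aic, x$sbic, x$hqic))
  invisible(x)
}

significance_stars <- function(p) {
  ifelse(is.na(p), "",
         ifelse(p < 0.01, "***", ifelse(p < 0.05, "**",
                ifelse(p < 0.10, "*", ""))))
}

# coefficient table: per response column, "estimate stars" over "(t)" rows
format_coef_table <- function(est, tval, pval) {
  stars <- significance_stars(pval)
  K <- nrow(est)
  out <- matrix("", 2L * ncol(est), K,
                dimnames = list(rep("", 2L * ncol(est)),
                                paste0(rownames(est), " (t)")))
  rn <- character(2L * ncol(est))
  for (j in seq_len(ncol(est))) {
    out[2L * j - 1L, ] <- paste0(formatC(est[, j], format = "g", digits = 4),
                                 stars[, j])
    out[2L * j, ] <- paste0("(", formatC(tval[, j], format = "f",
                                         digits = 2), ")")
    rn[2L * j - 1L] <- colnames(est)[j]
  }
  rownames(out) <- format(rn)
  out
}

#' @export
summary.varfit <- function(object, ...) {
  pval <- 2 * stats::pt(-abs(object$t_matrix), df = object$df_resid)
  structure(list(fit = object, pval = pval), class = "summary.varfit")
}

#' @export
print.summary.varfit <- function(x, ...) {
  fit <- x$fit
  print(fit)
  cat("\nCoefficients (t-values in parentheses; * p<0.10 ** p<0.05 *** p<0.01)\n")
  tab <- format_coef_table(fit$coef_matrix, fit$t_matrix, x$pval)
  print(tab, quote = FALSE, right = TRUE)
  invisible(x)
}

#' @export
simulate.varfit <- function(object, nsim = 1, seed = NULL,
                            n_rows = NULL, method = c("bootstrap",
                                                      "gaussian"), ...) {
  method <- match.arg(method)
  if (!is.null(seed)) set.seed(seed)
  p <- object$p
  K <- object$K
  n_res <- nrow(object$residuals)
  if (is.null(n_rows)) n_rows <- n_res + p
  sims <- vector("list", nsim)
  for (s in seq_len(nsim)) {
    e <- switch(method,
                bootstrap = object$residuals[
                  sample.int(n_res, n_rows - p, replace = TRUE), ,
                  drop = FALSE],
                gaussian = rmvn(n_rows - p, object$sigma_hat))
    sims[[s]] <- rebuild_series(object, e)
  }
  if (nsim == 1L) sims[[1L]] else sims
}

# rebuild a series from the fitted recursion, given innovation rows e
# (rows p+1..T); initial p rows are the fit's presample tail
rebuild_series <- function(fit, e) {
  p <- fit$p
  K <- fit$K
  n_new <- nrow(e) + p
  x <- matrix(NA_real_, n_new, K,
              dimnames = list(NULL, fit$var_names))
  pre <- fit$presample
  x[seq_len(p), ] <- pre[(nrow(pre) - p + 1L):nrow(pre), , drop = FALSE]
  if (nrow(e) > nrow(fit$exog) - fit$n_presample)
    stop("cannot rebuild more rows than the estimation sample provides")
  Z <- fit$exog[(fit$n_presample + 1L):(fit$n_presample + nrow(e)), ,
                drop = FALSE]
  for (t in (p + 1L):n_new) {
    state <- x[(t - p):(t - 1L), , drop = FALSE]
    x[t, ] <- var_forecast(fit$B, fit$A, state, Z[t - p, ]) + e[t - p, ]
  }
  x
}

#' Pool VAR fits across imputations by Rubin's rules
#'
#' Combines M per-imputation [var_fit()] results. For each scalar
#' coefficient: point estimate = mean of the M estimates; within-variance
#' `W` = mean squared standard error; between-variance `Bv` = variance of
#' the estimates across imputations; total variance `Tv = W + (1 + 1/M) Bv`;
#' pooled se = `sqrt(Tv)`; Rubin degrees of freedom
#' `(M - 1) (1 + W / ((1 + 1/M) Bv))^2` (infinite when `Bv = 0`; for M = 1
#' the single fit's residual df are used).
#'
#' @param fits list of `varfit` objects sharing the same specification.
#' @return An object of class `pooled_varfit` with pooled `est`, `se`, `t`,
#'   `p` and `df` matrices (rows = equations, columns = predictors), plus
#'   `B` and `A` in the same layout as a single fit. `coef`, `print` and
#'   `summary` methods are provided.
#' @export
pool_rubin <- function(fits) {
  if (inherits(fits, "varfit")) fits <- list(fits)
  M <- length(fits)
  if (M < 1) stop("need at least one fit")
  ref <- fits[[1L]]
  for (f in fits) {
    if (!inherits(f, "varfit")) stop("all elements must be varfit objects")
    if (f$p != ref$p || !identical(f$var_names, ref$var_names) ||
        !identical(f$exog_names, ref$exog_names) || f$n_eff != ref$n_eff)
      stop("all fits must share the same specification")
  }
  est_arr <- simplify2array(lapply(fits, `[[`, "coef_matrix"))
  se_arr <- simplify2array(lapply(fits, `[[`, "se_matrix"))
  dim(est_arr) <- dim(se_arr) <- c(nrow(ref$coef_matrix),
                                   ncol(ref$coef_matrix), M)
  qbar <- apply(est_arr, c(1L, 2L), mean)
  W <- apply(se_arr^2, c(1L, 2L), mean)
  Bv <- if (M > 1L) apply(est_arr, c(1L, 2L), stats::var)
        else array(0, dim(qbar))
  Tv <- W + (1 + 1 / M) * Bv
  se <- sqrt(Tv)
  df <- ifelse(Bv > 0, (M - 1) * (1 + W / ((1 + 1 / M) * Bv))^2, Inf)
  if (M == 1L) df[] <- ref$df_resid
  tval <- ifelse(se > 0, qbar / se, NA_real_)
  pval <- 2 * stats::pt(-abs(tval), df = df)
  dimnames(qbar) <- dimnames(se) <- dimnames(tval) <- dimnames(pval) <-
    dimnames(df) <- dimnames(W) <- dimnames(Bv) <- dimnames(Tv) <-
    dimnames(ref$coef_matrix)
  K <- ref$K
  B <- lapply(seq_len(ref$p), function(l) {
    out <- qbar[, (l - 1L) * K + seq_len(K), drop = FALSE]
    colnames(out) <- ref$var_names
    out
  })
  A <- qbar[, K * ref$p + seq_len(ref$m), drop = FALSE]
  structure(list(est = qbar, se = se, t = tval, p_value = pval, df = df,
                 W = W, between = Bv, total = Tv, M = M,
                 B = B, A = A, p = ref$p, K = K, m = ref$m,
                 var_names = ref$var_names, exog_names = ref$exog_names,
                 n_eff = ref$n_eff),
            class = "pooled_varfit")
}

#' @export
coef.pooled_varfit <- function(object, ...) object$est

#' @export
print.pooled_varfit <- function(x, ...) {
  cat(sprintf("Rubin-pooled VAR(%d): K = %d, M = %d imputations, n_eff = %d\n",
              x$p, x$K, x$M, x$n_eff))
  invisible(x)
}

#' @export
summary.pooled_varfit <- function(object, ...) {
  structure(list(fit = object), class = "summary.pooled_varfit")
}

#' @export
print.summary.pooled_varfit <- function(x, ...) {
  fit <- x$fit
  print(fit)
  cat("\nPooled coefficients (t in parentheses; * p<0.10 ** p<0.05 *** p<0.01)\n")
  tab <- format_coef_table(fit$est, fit$t, fit$p_value)
  print(tab, quote = FALSE, right = TRUE)
  invisible(x)
}
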