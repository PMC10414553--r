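#' Impulse-response function of a fitted VAR
#'
#' Traces the response of every variable over horizons `0..H` to a one-time
#' shock in one equation's error term. The moving-average matrices follow
#' the recursion `Phi_0 = I`, `Phi_h = sum_{l=1..min(h,p)} B_l Phi_{h-l}`.
#' For a non-orthogonalized IRF the impulse is `sd * e_impulse` with `sd`
#' the residual standard deviation of the impulse equation (the classic
#' "one-standard-deviation impulse to the error term"); set
#' `impulse_scale = "unit"` for a unit shock. For an orthogonalized IRF the
#' impulse is the corresponding column of the lower Cholesky factor of the
#' residual covariance under the given variable ordering, so contemporaneous
#' shock correlation is passed through at horizon 0.
#'
#' @param fit a [var_fit()] result, or a list with elements `B` (lag
#'   matrices) and `sigma_hat` for use with externally supplied
#'   coefficients.
#' @param impulse name (or index) of the shocked variable.
#' @param H largest horizon (>= 1). Default 12 lag periods.
#' @param ortho orthogonalize via Cholesky? Default `FALSE`.
#' @param order variable ordering for the Cholesky factor (default: panel
#'   column order). Ignored unless `ortho = TRUE`.
#' @param impulse_scale `"sd"` (default) or `"unit"`; ignored for
#'   orthogonalized IRFs, whose shocks are already on the residual-sd scale.
#' @return An object of class `varirf`: list with `responses`
#'   (`(H+1) x K`), `horizons`, `impulse`, band slots (`lower`, `upper`,
#'   `NULL` until [irf_bands()] fills them), and bookkeeping fields.
#' @examples
#' fit <- var_fit(make_benchmark_case(1, missing = FALSE)$complete)
#' compute_irf(fit, impulse = "CRP", H = 8)
#' @export
compute_irf <- function(fit, impulse, H = 12,
                        ortho = FALSE, order = NULL,
                        impulse_scale = c("sd", "unit")) {
  impulse_scale <- match.arg(impulse_scale)
  if (H < 1) stop("H must be >= 1")
  B <- fit$B
  if (is.matrix(B)) B <- list(B)
  K <- nrow(B[[1L]])
  vars <- fit$var_names %||% rownames(B[[1L]]) %||%
    paste0("V", seq_len(K))
  if (is.numeric(impulse)) impulse <- vars[impulse]
  if (!impulse %in% vars) stop("unknown impulse variable: ", impulse)
  j <- match(impulse, vars)
  sigma <- fit$sigma_hat
  if (ortho) {
    if (is.null(sigma)) stop("sigma_hat required for orthogonalized IRF")
    if (is.null(order)) order <- vars
    perm <- match(order, vars)
    if (anyNA(perm) || length(perm) != K)
      stop("order must be a permutation of the variable names")
    P <- matrix(0, K, K)
    ch <- tryCatch(t(chol(sigma[perm, perm, drop = FALSE])),
                   error = function(e)
                     stop("sigma_hat is not positive definite; ",
                          "cannot orthogonalize", call. = FALSE))
    P[perm, perm] <- ch
    v <- P[, j]
  } else {
    s <- if (impulse_scale == "sd") {
      if (is.null(sigma)) stop("sigma_hat required for sd-scaled impulse")
      sqrt(sigma[j, j])
    } else 1
    v <- numeric(K)
    v[j] <- s
  }
  resp <- matrix(NA_real_, H + 1L, K, dimnames = list(NULL, vars))
  phi <- vector("list", H + 1L)
  phi[[1L]] <- diag(K)
  resp[1L, ] <- v
  p <- length(B)
  for (h in seq_len(H)) {
    acc <- matrix(0, K, K)
    for (l in seq_len(min(h, p)))
      acc <- acc + B[[l]] %*% phi[[h - l + 1L]]
    phi[[h + 1L]] <- acc
    resp[h + 1L, ] <- drop(acc %*% v)
  }
  structure(list(responses = resp, horizons = 0:H, impulse = impulse,
                 lower = NULL, upper = NULL, ortho = ortho,
                 ordering = if (ortho) order else vars,
                 impulse_vector = v, impulse_scale = impulse_scale,
                 var_names = vars, H = H, n_boot = 0L,
                 n_unstable_redraws = 0L),
            class = "varirf")
}

#' @export
print.varirf <- function(x, ...) {
  cat(sprintf("IRF: %s impulse to %s, horizons 0..%d%s\n",
              if (x$ortho) "orthogonalized"
              else paste0("non-orthogonalized (", x$impulse_scale, " scale)"),
              x$impulse, x$H,
              if (is.null(x$lower)) ""
              else sprintf(", 95%% bands from %d bootstrap replicates",
                           x$n_boot)))
  print(round(cbind(horizon = x$horizons, x$responses), 4))
  invisible(x)
}

#' Residual-bootstrap confidence bands for an IRF
#'
#' Resamples the fitted residual rows with replacement, rebuilds the series
#' from the initial `p` rows through the fitted recursion, refits the VAR,
#' and recomputes the IRF. Bands are pointwise 2.5/97.5 percentiles over
#' replicates. Replicates whose refit is non-stationary are re-drawn (with a
#' cap; the number of re-draws is recorded). With an [impute_chained()]
#' result the replicates are distributed evenly over the M completed panels
#' and the point response is the average of the per-panel IRFs.
#'
#' @param x a complete [regular_panel] or an `imputation_set`.
#' @param impulse shocked variable name.
#' @param H largest horizon.
#' @param n_boot bootstrap replicates (>= 100). Default 500.
#' @param seed integer seed or `NULL`.
#' @param p,exog VAR specification, as in [var_fit()].
#' @param ortho,order,impulse_scale as in [compute_irf()].
#' @param band_type `"pointwise"` (default): percentile 2.5/97.5 bands per
#'   horizon, the usual IRF plot bands; their joint coverage across
#'   horizons is below the nominal level. `"simultaneous"`: sup-t bands
#'   calibrated so the whole response path stays inside the band with 95%
#'   probability -- the right choice when asking whether a response differs
#'   from zero *anywhere* over the horizon window.
#' @param require_stable re-draw unstable replicates (default `TRUE`).
#' @return A `varirf` with `lower` and `upper` filled in.
#' @export
irf_bands <- function(x, impulse, H = 12, n_boot = 500, seed = NULL,
                      p = 1, exog = NULL, ortho = FALSE, order = NULL,
                      impulse_scale = c("sd", "unit"),
                      band_type = c("pointwise", "simultaneous"),
                      require_stable = TRUE) {
  impulse_scale <- match.arg(impulse_scale)
  band_type <- match.arg(band_type)
  if (n_boot < 100) stop("n_boot must be >= 100")
  if (!is.null(seed)) set.seed(derive_seed(seed, 3L))
  panels <- if (inherits(x, "imputation_set")) x$panels else list(x)
  n_panels <- length(panels)
  share <- rep(n_boot %/% n_panels, n_panels)
  if (n_boot %% n_panels)
    share[seq_len(n_boot %% n_panels)] <- share[seq_len(n_boot %% n_panels)] + 1L
  point_acc <- NULL
  redraws <- 0L
  max_redraws <- 20L * n_boot
  got <- 0L
  K <- NULL
  all_draws <- NULL
  for (i in seq_len(n_panels)) {
    fit <- var_fit(panels[[i]], p = p, exog = exog)
    irf_point <- compute_irf(fit, impulse, H, ortho, order, impulse_scale)
    point_acc <- if (is.null(point_acc)) irf_point$responses / n_panels
                 else point_acc + irf_point$responses / n_panels
    if (is.null(all_draws)) {
      K <- ncol(irf_point$responses)
      all_draws <- array(NA_real_, c(n_boot, H + 1L, K))
    }
    n_res <- nrow(fit$residuals)
    b <- 0L
    while (b < share[i]) {
      e <- fit$residuals[sample.int(n_res, n_res, replace = TRUE), ,
                         drop = FALSE]
      xb <- rebuild_series(fit, e)
      refit <- tryCatch(var_fit(xb, p = p,
                                exog = fit$exog[, -1L, drop = FALSE]),
                        error = function(err) NULL)
      ok <- !is.null(refit) &&
        (!require_stable || check_stability(refit)$stable)
      if (!ok) {
        redraws <- redraws + 1L
        if (redraws > max_redraws)
          stop("too many unstable bootstrap replicates (", redraws, ")")
        next
      }
      b <- b + 1L
      got <- got + 1L
      all_draws[got, , ] <- compute_irf(refit, impulse, H, ortho, order,
                                        impulse_scale)$responses
    }
  }
  template <- compute_irf(var_fit(panels[[1L]], p = p, exog = exog),
                          impulse, H, ortho, order, impulse_scale)
  if (band_type == "pointwise") {
    lower <- apply(all_draws, c(2L, 3L), stats::quantile, probs = 0.025,
                   names = FALSE)
    upper <- apply(all_draws, c(2L, 3L), stats::quantile, probs = 0.975,
                   names = FALSE)
  } else {
    # sup-t: per response variable, scale horizon-wise bootstrap sd by the
    # 95th percentile of the max studentized deviation over horizons
    lower <- upper <- matrix(NA_real_, H + 1L, K)
    for (k in seq_len(K)) {
      ctr <- point_acc[, k]
      s <- apply(all_draws[, , k, drop = FALSE], 2L, stats::sd)
      dev <- abs(sweep(all_draws[, , k], 2L, ctr, `-`))
      pos <- s > 0
      m <- if (any(pos))
        apply(sweep(dev[, pos, drop = FALSE], 2L, s[pos], `/`), 1L, max)
      else rep(0, n_boot)
      cmult <- stats::quantile(m, 0.95, names = FALSE)
      lower[, k] <- ctr - cmult * s
      upper[, k] <- ctr + cmult * s
    }
  }
  dimnames(lower) <- dimnames(upper) <- dimnames(template$responses)
  out <- template
  out$responses <- point_acc
  out$lower <- lower
  out$upper <- upper
  out$n_boot <- as.integer(n_boot)
  out$band_type <- band_type
  out$n_unstable_redraws <- redraws
  if (redraws > 0L)
    message(redraws, " unstable bootstrap replicates were re-drawn")
  out
}

#' Return-to-baseline horizon of an IRF band
#'
#' The smallest horizon `h*` such that the 95% band of the chosen response
#' contains zero at `h*` and at every later horizon up to `H` -- the point
#' after which the response is no longer distinguishable from baseline. A
#' band that always contains zero gives 0; if zero is excluded at the last
#' horizon, the sentinel `Inf` ("never within H") is returned.
#'
#' @param result a `varirf` with bands (see [irf_bands()]).
#' @param response response variable name.
#' @return A single numeric horizon (possibly `Inf`).
#' @export
return_to_baseline <- function(result, response) {
  stopifnot(inherits(result, "varirf"))
  if (is.null(result$lower))
    stop("result has no confidence bands; run irf_bands() first")
  if (!response %in% result$var_names)
    stop("unknown response variable: ", response)
  lo <- result$lower[, response]
  hi <- result$upper[, response]
  contains0 <- lo <= 0 & hi >= 0
  excluded <- which(!contains0)
  if (length(excluded) == 0L) return(0)
  last_excluded <- max(excluded)
  if (last_excluded == length(contains0)) return(Inf)
  result$horizons[last_excluded + 1L]
}

#' @export
plot.varirf <- function(x, vars = x$var_names, mfrow = NULL, ...) {
  K <- length(vars)
  if (is.null(mfrow)) mfrow <- c(ceiling(K / 2), min(K, 2))
  op <- graphics::par(mfrow = mfrow, mar = c(4, 4, 2.5, 1))
  on.exit(graphics::par(op))
  h <- x$horizons
  for (v in vars) {
    r <- x$responses[, v]
    ylim <- range(0, r, x$lower[, v], x$upper[, v], na.rm = TRUE)
    graphics::plot(h, r, type = "n", ylim = ylim,
                   xlab = "horizon (lag periods)", ylab = "response",
                   main = sprintf("%s -> %s", x$impulse, v), ...)
    if (!is.null(x$lower))
      graphics::polygon(c(h, rev(h)),
                        c(x$lower[, v], rev(x$upper[, v])),
                        col = grDevices::grey(0.9), border = NA)
    graphics::abline(h = 0, col = "grey50", lty = 2)
    graphics::lines(h, r, lwd = 2)
  }
  invisible(x)
}
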