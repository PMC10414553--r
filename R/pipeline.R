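#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end analysis run: gridding,
#' restriction, imputation, lag order, IRFs, association and the headline
#' coefficients to report. The defaults mirror an intensively monitored
#' single-patient biomarker analysis: 6-day lag grid, restriction to the
#' densely sampled first 1438 days, 20 imputations with a positivity bound
#' at zero, lag order 1, and a CRP impulse traced over 12 periods.
#'
#' @param step grid step in days.
#' @param endogenous ordered endogenous variable names (>= 2); the order
#'   also fixes the Cholesky ordering of orthogonalized IRFs.
#' @param event_days optional treatment administration days, expanded to a
#'   per-row pulse indicator covariate.
#' @param day_cutoff keep grid rows at or below this day (`Inf` to disable).
#' @param m_imputations,n_iter,lower_bound imputation settings
#'   (see [impute_chained()]).
#' @param lags fixed lag order, or `NULL` to select by SBIC up to `p_max`.
#' @param p_max largest candidate lag order when selecting.
#' @param irf_impulses variables to shock (default first endogenous).
#' @param irf_horizons largest IRF horizon.
#' @param irf_order Cholesky ordering (default: `endogenous`).
#' @param ortho orthogonalize IRFs? Default `FALSE`.
#' @param n_boot IRF bootstrap replicates; 0 skips the bands.
#' @param headline list of `c(from, to)` lag-1 coefficient pairs to report;
#'   defaults to the inflammation-to-organ chain CRP->AP, AP->proteinuria
#'   and the direct CRP->proteinuria link.
#' @param alpha significance level for the headline report (default 0.05).
#' @param seed master seed for every stochastic stage.
#' @param sensitivity named list of sensitivity toggles, see
#'   [sensitivity_suite()].
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(step = 6,
                            endogenous = c("CRP", "AP", "NTproBNP",
                                           "proteinuria"),
                            event_days = NULL,
                            day_cutoff = 1438,
                            m_imputations = 20, n_iter = 10,
                            lower_bound = 0,
                            lags = 1, p_max = NULL,
                            irf_impulses = endogenous[1L],
                            irf_horizons = 12,
                            irf_order = endogenous,
                            ortho = FALSE,
                            n_boot = 200,
                            headline = list(c("CRP", "AP"),
                                            c("AP", "proteinuria"),
                                            c("CRP", "proteinuria")),
                            alpha = 0.05,
                            seed = 1,
                            sensitivity = list()) {
  if (length(endogenous) < 2L) stop("need at least 2 endogenous variables")
  if (is.null(lags) && is.null(p_max))
    stop("give a fixed lag order or a p_max for selection")
  if (!is.null(lags) && lags < 1) stop("lag order must be >= 1")
  structure(list(step = step, endogenous = endogenous,
                 event_days = event_days, day_cutoff = day_cutoff,
                 m_imputations = m_imputations, n_iter = n_iter,
                 lower_bound = lower_bound, lags = lags, p_max = p_max,
                 irf_impulses = irf_impulses, irf_horizons = irf_horizons,
                 irf_order = irf_order, ortho = ortho, n_boot = n_boot,
                 headline = headline, alpha = alpha, seed = seed,
                 sensitivity = sensitivity,
                 use_lagged_imputation = TRUE,
                 extra_exog = NULL, gap_covariate = FALSE),
            class = "pipeline_config")
}

#' Run the end-to-end single-patient VAR analysis
#'
#' Executes the full chain on one subject's data: regularize onto the lag
#' grid, restrict to the configured day span, multiply impute with a
#' positivity bound, fix or select the lag order, fit the VAR per completed
#' panel, pool by Rubin's rules, compute the requested impulse-response
#' functions (with bootstrap bands if `n_boot > 0`), and correlate the
#' observed (pre-imputation) panel. Identical configuration and seed give
#' identical output.
#'
#' @param x a [clinical_series] or an (incomplete) [regular_panel].
#' @param config a [pipeline_config].
#' @param quiet suppress stage log messages (default `TRUE`).
#' @return An object of class `nof1_run`: list with `panel` (pre-imputation,
#'   restricted), `imputation`, `p` (lag order used), `lag_selection`
#'   (or `NULL`), `fits`, `pooled`, `irf` (named list of `varirf`),
#'   `correlations`, `headline` (data.frame of the reported coefficients
#'   with pooled estimate, se, t, p, stars and a `significant` flag at
#'   `config$alpha`), `config` and `seed`.
#' @examples
#' bench <- make_benchmark_case(seed = 7)
#' cfg <- pipeline_config(m_imputations = 3, n_iter = 3, n_boot = 0, seed = 7)
#' run <- run_pipeline(bench$panel, cfg)
#' run$headline
#' @export
run_pipeline <- function(x, config = pipeline_config(), quiet = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (!quiet) message("[nof1var] ", sprintf(...))
  stage <- "regularize"
  out <- tryCatch({
    panel <- if (inherits(x, "clinical_series"))
      regularize_to_grid(x, step = config$step)
    else if (inherits(x, "regular_panel")) x
    else stop("x must be a clinical_series or a regular_panel")
    say("regularized: %d rows x %d vars, step %g days",
        nrow(panel), ncol(panel), panel_step(panel))

    stage <- "restrict"
    keep <- panel_days(panel) <= config$day_cutoff
    if (!any(keep)) stop("day_cutoff excludes every grid row")
    panel <- regular_panel(panel_matrix(panel)[keep, , drop = FALSE],
                           step = panel_step(panel), t0 = attr(panel, "t0"))
    missing_endo <- setdiff(config$endogenous, colnames(panel))
    if (length(missing_endo))
      stop("endogenous variables absent from the data: ",
           paste(missing_endo, collapse = ", "))
    endo_panel <- regular_panel(
      panel_matrix(panel)[, config$endogenous, drop = FALSE],
      step = panel_step(panel), t0 = attr(panel, "t0"))
    say("restricted to day <= %g: %d rows", config$day_cutoff,
        nrow(endo_panel))

    stage <- "exogenous design"
    exog <- NULL
    if (!is.null(config$event_days)) {
      exog <- cbind(exog,
                    treatment = make_pulse_indicator(endo_panel,
                                                     config$event_days))
    }
    if (isTRUE(config$gap_covariate))
      exog <- cbind(exog, gap = make_gap_covariate(endo_panel))
    if (!is.null(config$extra_exog)) {
      extra <- setdiff(config$extra_exog, colnames(panel))
      if (length(extra))
        stop("extra exogenous columns absent: ",
             paste(extra, collapse = ", "))
      em <- panel_matrix(panel)[, config$extra_exog, drop = FALSE]
      if (anyNA(em)) {
        # carry the last observation forward; exogenous columns must be
        # complete and are not themselves modelled
        for (j in seq_len(ncol(em))) {
          v <- em[, j]
          obs <- which(!is.na(v))
          if (length(obs) == 0L)
            stop("extra exogenous column fully missing: ",
                 config$extra_exog[j])
          idx <- cummax(ifelse(is.na(v), 0L, seq_along(v)))
          idx[idx == 0L] <- obs[1L]  # backfill before first observation
          em[, j] <- v[idx]
        }
      }
      exog <- cbind(exog, em)
    }

    stage <- "imputation"
    imp <- impute_chained(endo_panel, M = config$m_imputations,
                          n_iter = config$n_iter,
                          lower_bound = config$lower_bound,
                          seed = config$seed,
                          lagged_covariates = config$use_lagged_imputation)
    say("imputed: M = %d, %d cells", imp$M, sum(imp$mask))

    stage <- "lag selection"
    lag_sel <- NULL
    p <- config$lags
    if (is.null(p)) {
      lag_sel <- select_lag_order(imp$panels[[1L]], p_max = config$p_max,
                                  exog = exog)
      p <- unname(attr(lag_sel, "selected")["sbic"])
      say("selected lag order p = %d by SBIC", p)
    }

    stage <- "VAR estimation"
    fits <- lapply(imp$panels, var_fit, p = p, exog = exog)
    pooled <- pool_rubin(fits)
    say("fitted and pooled %d VAR(%d) fits", length(fits), p)

    stage <- "impulse responses"
    irfs <- list()
    for (imp_var in config$irf_impulses) {
      irfs[[imp_var]] <- if (config$n_boot > 0) {
        irf_bands(imp, impulse = imp_var, H = config$irf_horizons,
                  n_boot = config$n_boot, seed = config$seed, p = p,
                  exog = exog, ortho = config$ortho,
                  order = config$irf_order)
      } else {
        compute_irf(fits[[1L]], impulse = imp_var,
                    H = config$irf_horizons, ortho = config$ortho,
                    order = config$irf_order)
      }
    }

    stage <- "association"
    correlations <- spearman_matrix(endo_panel)

    stage <- "report"
    headline <- headline_table(pooled, config$headline, config$alpha)
    structure(list(panel = endo_panel, imputation = imp, p = p,
                   lag_selection = lag_sel, fits = fits, pooled = pooled,
                   irf = irfs, correlations = correlations,
                   headline = headline, config = config,
                   seed = config$seed),
              class = "nof1_run")
  }, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         "\n  hint: check the inputs and configuration for this stage",
         call. = FALSE)
  })
  out
}

headline_table <- function(pooled, pairs, alpha) {
  rows <- lapply(pairs, function(pr) {
    from <- pr[1L]; to <- pr[2L]
    col <- paste0(from, ".l1")
    if (!to %in% rownames(pooled$est) || !col %in% colnames(pooled$est))
      stop("headline pair not in the model: ", from, " -> ", to)
    data.frame(from = from, to = to,
               estimate = pooled$est[to, col],
               se = pooled$se[to, col],
               t = pooled$t[to, col],
               p_value = pooled$p_value[to, col],
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab$stars <- significance_stars(tab$p_value)
  tab$significant <- !is.na(tab$p_value) & tab$p_value < alpha
  rownames(tab) <- NULL
  tab
}

#' @export
print.nof1_run <- function(x, ...) {
  cat(sprintf("nof1var pipeline run (seed %s): T = %d rows, K = %d, VAR(%d), M = %d\n",
              format(x$seed), nrow(x$panel), ncol(x$panel), x$p,
              x$imputation$M))
  cat("\nHeadline lag-1 coefficients (Rubin-pooled):\n")
  tab <- x$headline
  tab$estimate <- signif(tab$estimate, 4)
  tab$se <- signif(tab$se, 3)
  tab$t <- round(tab$t, 2)
  tab$p_value <- signif(tab$p_value, 3)
  print(tab, row.names = FALSE)
  cat("(* p<0.10 ** p<0.05 *** p<0.01)\n")
  invisible(x)
}

#' Sensitivity suite over analysis variants
#'
#' Re-runs [run_pipeline()] under each configured variant and tabulates the
#' sign and significance of the headline coefficients against the base run.
#' Supported toggles in `config$sensitivity`:
#' \describe{
#'   \item{substitute}{named character vector, e.g. `c(CRP = "SAA")`:
#'     replace endogenous variables by alternatives present in the data.}
#'   \item{alt_imputation}{`TRUE`: switch the chained imputation models to
#'     the alternative covariate set (same-row-only if the base run uses
#'     lagged covariates, and vice versa).}
#'   \item{timing_covariates}{`TRUE`: add the inter-measurement gap length
#'     (and the treatment pulse, if `event_days` is set) as exogenous
#'     covariates.}
#'   \item{day_cutoff}{numeric: alternative sample-restriction day.}
#'   \item{extra_lags}{integer vector of alternative lag orders, e.g.
#'     `c(2, 3)` (lag-1 headline coefficients are compared).}
#'   \item{long_steps}{numeric vector of longer grid steps in days, e.g.
#'     `c(30, 90, 180, 270, 360)`; the panel is re-gridded (needs enough
#'     rows to estimate, variants that run out of data are recorded as
#'     failed).}
#'   \item{extra_exog}{character: additional observed columns entered as
#'     exogenous covariates.}
#' }
#'
#' @param x input data as in [run_pipeline()].
#' @param config a [pipeline_config] whose `sensitivity` list holds the
#'   toggles; an empty list runs only the base analysis.
#' @param quiet suppress stage logs.
#' @return A `sensitivity_table`: data.frame with one row per variant and
#'   headline pair (estimate, sign, significant, `confirmed` = same sign
#'   and significance as the base run; failed variants carry the error
#'   message), with the base run as attribute `base_run`.
#' @export
sensitivity_suite <- function(x, config = pipeline_config(), quiet = TRUE) {
  base <- run_pipeline(x, config, quiet = quiet)
  rows <- headline_rows("base", base$headline, base$headline)
  sens <- config$sensitivity
  variants <- list()
  if (!is.null(sens$substitute)) {
    cfg <- config
    sub <- sens$substitute
    idx <- match(names(sub), cfg$endogenous)
    if (anyNA(idx)) stop("substitute names must be endogenous variables")
    cfg$endogenous[idx] <- unname(sub)
    cfg$irf_order <- cfg$endogenous
    cfg$irf_impulses <- cfg$endogenous[match(config$irf_impulses,
                                             config$endogenous)]
    cfg$headline <- lapply(cfg$headline, function(pr) {
      pr[pr %in% names(sub)] <- sub[pr[pr %in% names(sub)]]
      pr
    })
    variants$substitute <- cfg
  }
  if (isTRUE(sens$alt_imputation)) {
    cfg <- config
    cfg$use_lagged_imputation <- !config$use_lagged_imputation
    variants$alt_imputation <- cfg
  }
  if (isTRUE(sens$timing_covariates)) {
    cfg <- config; cfg$gap_covariate <- TRUE
    variants$timing_covariates <- cfg
  }
  if (!is.null(sens$day_cutoff)) {
    for (dc in sens$day_cutoff) {
      cfg <- config; cfg$day_cutoff <- dc
      variants[[paste0("day_cutoff_", dc)]] <- cfg
    }
  }
  if (!is.null(sens$extra_lags)) {
    for (p in sens$extra_lags) {
      cfg <- config; cfg$lags <- p; cfg$p_max <- NULL
      variants[[paste0("lags_", p)]] <- cfg
    }
  }
  if (!is.null(sens$long_steps)) {
    for (s in sens$long_steps) {
      cfg <- config; cfg$step <- s; cfg$regrid <- TRUE
      variants[[paste0("step_", s)]] <- cfg
    }
  }
  if (!is.null(sens$extra_exog)) {
    cfg <- config; cfg$extra_exog <- sens$extra_exog
    variants$extra_exog <- cfg
  }
  for (vn in names(variants)) {
    cfg <- variants[[vn]]
    input <- x
    if (isTRUE(cfg$regrid)) {
      series <- if (inherits(x, "clinical_series")) x
                else as_clinical_series(x)
      input <- series
    }
    res <- tryCatch(run_pipeline(input, cfg, quiet = quiet),
                    error = function(e) conditionMessage(e))
    if (is.character(res)) {
      rows <- rbind(rows, data.frame(
        variant = vn, from = NA, to = NA, estimate = NA_real_,
        sign = NA_integer_, significant = NA, confirmed = NA,
        error = res, stringsAsFactors = FALSE))
    } else {
      rows <- rbind(rows, headline_rows(vn, res$headline, base$headline))
    }
  }
  structure(rows, base_run = base,
            class = c("sensitivity_table", "data.frame"))
}

headline_rows <- function(variant, headline, base_headline) {
  data.frame(variant = variant,
             from = headline$from, to = headline$to,
             estimate = headline$estimate,
             sign = sign(headline$estimate),
             significant = headline$significant,
             confirmed = sign(headline$estimate) ==
               sign(base_headline$estimate) &
               headline$significant == base_headline$significant,
             error = "", stringsAsFactors = FALSE)
}

#' @export
print.sensitivity_table <- function(x, ...) {
  cat("Sensitivity suite: headline coefficients by variant\n")
  df <- as.data.frame(x)
  df$estimate <- signif(df$estimate, 4)
  print(df, row.names = FALSE)
  invisible(x)
}
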