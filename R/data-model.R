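#' Clinical measurement series
#'
#' A long-format container for irregularly sampled, single-subject clinical
#' measurements. Times are expressed in days since the first observation,
#' so the earliest record is always at day 0.
#'
#' @param day numeric vector of observation days (finite, non-negative after
#'   shifting; the constructor shifts so that `min(day) == 0`).
#' @param variable character vector of variable names (non-empty strings).
#' @param value numeric vector of measured values (finite).
#'
#' @return An object of class `clinical_series`: a `data.frame` with columns
#'   `day`, `variable`, `value`, and an attribute `variables` holding the
#'   variable catalog in first-appearance order.
#'
#' @details Duplicate `(day, variable)` pairs are rejected: a measurement at a
#'   given day is the subject's state and must be unique.
#'
#' @examples
#' s <- clinical_series(c(10, 16, 22), rep("CRP", 3), c(5, 7, 4))
#' s$day  # 0 6 12
#' @export
clinical_series <- function(day, variable, value) {
  day <- as.numeric(day)
  variable <- as.character(variable)
  value <- as.numeric(value)
  n <- length(day)
  if (length(variable) != n || length(value) != n)
    stop("day, variable and value must have equal length")
  if (n == 0L) stop("a clinical series needs at least one record")
  if (!all(is.finite(day))) stop("all observation days must be finite")
  if (!all(is.finite(value))) stop("all values must be finite")
  if (any(!nzchar(variable)) || anyNA(variable))
    stop("variable names must be non-empty")
  day <- day - min(day)
  key <- paste(format(day, digits = 15), variable, sep = "\r")
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1L]
    stop("duplicate (day, variable) record: ",
         sub("\r", " / ", d), call. = FALSE)
  }
  out <- data.frame(day = day, variable = variable, value = value,
                    stringsAsFactors = FALSE)
  attr(out, "variables") <- unique(variable)
  class(out) <- c("clinical_series", "data.frame")
  out
}

#' Read a long-format measurement CSV
#'
#' Reads a comma-separated file with columns `day`, `variable`, `value` into
#' a [clinical_series]. Rows whose value matches one of `missing_tokens` are
#' dropped; times are shifted so the earliest remaining record is day 0.
#'
#' @param path path to a CSV file with a header containing `day`, `variable`
#'   and `value` columns (extra columns are ignored).
#' @param missing_tokens character vector of value strings treated as
#'   missing and dropped (default: empty string, `"NA"`, `"NaN"`).
#'
#' @return A [clinical_series].
#' @export
read_series_csv <- function(path, missing_tokens = c("", "NA", "NaN")) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", check.names = TRUE,
                        na.strings = character(0))
  need <- c("day", "variable", "value")
  if (!all(need %in% names(df)))
    stop("header must contain columns: ", paste(need, collapse = ", "))
  keep <- !(df$value %in% missing_tokens)
  df <- df[keep, , drop = FALSE]
  if (nrow(df) == 0L) stop("no non-missing records in ", path)
  lines <- which(keep) + 1L  # original file line numbers (header = line 1)
  day <- suppressWarnings(as.numeric(df$day))
  value <- suppressWarnings(as.numeric(df$value))
  bad <- which(!is.finite(day) | !is.finite(value))
  if (length(bad))
    stop("malformed row at line ", lines[bad[1L]], " of ", path)
  clinical_series(day, df$variable, value)
}

#' Regular measurement panel
#'
#' A fixed-step T x K grid of measurements, the unit of all modelling. Cells
#' are finite reals or `NA` (missing). Column order is fixed at construction
#' and defines the Cholesky ordering used by orthogonalized impulse-response
#' functions downstream.
#'
#' @param values numeric matrix (T x K) with `NA` for missing cells;
#'   column names are the variable names.
#' @param step grid step in days (> 0).
#' @param t0 day of the first grid row (default 0).
#' @return An object of class `regular_panel` (a numeric matrix with `step`
#'   and `t0` attributes).
#' @seealso [regularize_to_grid()], [panel_days()]
#' @export
regular_panel <- function(values, step, t0 = 0) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (any(is.infinite(values))) stop("panel cells must be finite or NA")
  if (!is.numeric(step) || length(step) != 1L || !is.finite(step) || step <= 0)
    stop("step must be a single positive number of days")
  if (is.null(colnames(values)))
    colnames(values) <- paste0("V", seq_len(ncol(values)))
  structure(values, step = as.numeric(step), t0 = as.numeric(t0),
            class = c("regular_panel", "matrix", "array"))
}

#' @export
print.regular_panel <- function(x, ...) {
  cat(sprintf("Regular panel: %d rows x %d variables, step = %g days, t0 = %g\n",
              nrow(x), ncol(x), panel_step(x), attr(x, "t0")))
  cat("Variables:", paste(colnames(x), collapse = ", "), "\n")
  n_missing <- sum(is.na(x))
  cat(sprintf("Missing cells: %d of %d (%.1f%%)\n", n_missing, length(x),
              100 * n_missing / length(x)))
  invisible(x)
}

#' @rdname regular_panel
#' @param panel a `regular_panel`.
#' @export
panel_step <- function(panel) attr(panel, "step")

#' Grid days of a regular panel
#'
#' @param panel a `regular_panel`.
#' @return Numeric vector `t0 + (0:(T-1)) * step`.
#' @export
panel_days <- function(panel) {
  attr(panel, "t0") + (seq_len(nrow(panel)) - 1) * panel_step(panel)
}

# strip panel class/attributes down to a plain double matrix
panel_matrix <- function(panel) {
  m <- unclass(panel)
  attr(m, "step") <- NULL
  attr(m, "t0") <- NULL
  m
}

#' Regularize an irregular series onto a fixed lag grid
#'
#' Bins observations into half-open intervals `[k*step, (k+1)*step)` starting
#' at day 0. Within a bin, the last (most recent) observation of a variable
#' wins: the latest clinical value is taken as the subject's state for that
#' lag period. Bins without an observation are `NA`.
#'
#' @param series a [clinical_series].
#' @param step grid step in days (> 0); 6 days reflects a typical mean
#'   inter-measurement spacing for an intensively monitored patient.
#' @return A [regular_panel] with `T = floor(last_day / step) + 1` rows and
#'   one column per cataloged variable, in catalog order.
#' @examples
#' s <- clinical_series(c(0, 5, 13), rep("A", 3), c(10, 11, 12))
#' regularize_to_grid(s, step = 6)  # rows: 11, NA, 12
#' @export
regularize_to_grid <- function(series, step = 6) {
  if (!inherits(series, "clinical_series"))
    stop("series must be a clinical_series")
  if (!is.numeric(step) || length(step) != 1L || !is.finite(step) || step <= 0)
    stop("step must be a single positive number of days")
  vars <- attr(series, "variables")
  n_rows <- floor(max(series$day) / step) + 1L
  m <- matrix(NA_real_, n_rows, length(vars), dimnames = list(NULL, vars))
  ord <- order(series$day)  # later observations overwrite earlier in-bin ones
  bin <- floor(series$day[ord] / step) + 1L
  j <- match(series$variable[ord], vars)
  m[cbind(bin, j)] <- series$value[ord]
  regular_panel(m, step = step, t0 = 0)
}

#' Recover the implied observed series from a panel
#'
#' Inverse of [regularize_to_grid()] up to in-bin collapsing: every observed
#' cell becomes one record at its grid day.
#'
#' @param panel a [regular_panel].
#' @return A [clinical_series].
#' @export
as_clinical_series <- function(panel) {
  m <- panel_matrix(panel)
  idx <- which(!is.na(m), arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("panel has no observed cells")
  days <- panel_days(panel)[idx[, 1L]]
  clinical_series(days, colnames(m)[idx[, 2L]], m[idx])
}

#' Per-variable observation counts
#'
#' @param panel a [regular_panel].
#' @return A `data.frame` with columns `variable`, `observed` (non-missing
#'   cells) and `total` (grid rows).
#' @export
observation_counts <- function(panel) {
  m <- panel_matrix(panel)
  data.frame(variable = colnames(m),
             observed = colSums(!is.na(m)),
             total = nrow(m),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Myocardial tracer retention index
#'
#' Percentage of myocardial tracer retained between an early and a late PET
#' frame: `RI = 100 * SUV_late / SUV_early`. An RI of 100% means no washout;
#' 0% means complete washout.
#'
#' @param suv_early mean standardized uptake value of the early (0-5 min)
#'   frame; must be > 0.
#' @param suv_late mean standardized uptake value of the late (15-20 min)
#'   frame; must be >= 0.
#' @return Retention index in percent. Vectorized.
#' @examples
#' retention_index(10, 5.8)  # 58
#' @export
retention_index <- function(suv_early, suv_late) {
  if (!all(is.finite(suv_early)) || !all(is.finite(suv_late)))
    stop("SUV inputs must be finite")
  if (any(suv_early <= 0)) stop("suv_early must be positive")
  if (any(suv_late < 0)) stop("suv_late must be non-negative")
  100 * suv_late / suv_early
}

#' Write / read a wide panel CSV
#'
#' Wide CSV serialization of a [regular_panel]: first column `day`, one
#' column per variable, missing cells written as empty fields.
#'
#' @param panel a `regular_panel`.
#' @param path output (input) file path.
#' @return `write_panel_csv` returns `path` invisibly; `read_panel_csv`
#'   returns a `regular_panel` (the step is inferred from the day column).
#' @export
write_panel_csv <- function(panel, path) {
  df <- data.frame(day = panel_days(panel), panel_matrix(panel),
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_panel_csv
#' @export
read_panel_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE,
                        na.strings = c("", "NA", "NaN"))
  if (names(df)[1L] != "day") stop("first column must be 'day'")
  day <- df$day
  if (nrow(df) < 2L) stop("panel CSV needs at least two rows")
  steps <- diff(day)
  if (max(steps) - min(steps) > 1e-8) stop("day column is not a regular grid")
  regular_panel(as.matrix(df[, -1L, drop = FALSE]),
                step = steps[1L], t0 = day[1L])
}
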