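#' Reference lag-1 coefficient matrix for a four-marker amyloidosis panel
#'
#' Loads the lag-1 coefficient matrix of a single-patient AA amyloidosis
#' VAR(1) over the markers AP (alkaline phosphatase, hepatic), NT-proBNP
#' (cardiac), proteinuria (renal) and CRP (inflammatory activity), as
#' reported in a published case analysis. Rows are responding variables,
#' columns are lagged predictors: entry `[i, j]` is the change in variable
#' i one lag period (about 6 days) after a one-unit increase in variable j.
#' Useful as a fixed input for forecast and impulse-response worked
#' examples, e.g. `amyloid_case_coefficients()["AP", "CRP"]` is 1.40: a
#' one-unit CRP increase raises predicted AP by 1.40 units one lag later.
#'
#' @return A 4 x 4 named numeric matrix.
#' @examples
#' B <- amyloid_case_coefficients()
#' var_forecast(B, state = c(0, 0, 0, 1))  # response to a unit CRP state
#' @export
amyloid_case_coefficients <- function() {
  path <- system.file("extdata", "amyloidosis_var1_coefficients.csv",
                      package = "nof1var", mustWork = TRUE)
  df <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -1L])
  rownames(m) <- df$response
  m
}
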