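#' Pairwise Spearman correlation with pairwise-complete observations
#'
#' For every variable pair, the rows where both are observed are ranked
#' (average ranks for ties) and the product-moment correlation of the ranks
#' is taken -- the tie-correct form of Spearman's rho. Two-sided p-values
#' use the t approximation `t = rho sqrt((n - 2) / (1 - rho^2))` on `n - 2`
#' df; for small pairs (`n <= exact_max`, default 10) an exact permutation
#' p-value over all distinct rank arrangements is computed instead. Pairs
#' with fewer than 3 complete rows, or with a constant member, are flagged
#' not-available (`NA`).
#'
#' Note for pooled longitudinal data from a single subject: repeated
#' measures are autocorrelated, so these p-values are anti-conservative;
#' they describe association, not confirmatory inference.
#'
#' @param panel a [regular_panel] (missing cells allowed) with K >= 2
#'   columns, or a plain numeric matrix.
#' @param exact_max use the exact permutation p-value when the
#'   pairwise-complete count is at most this (set 0 to disable). Default 10.
#' @param adjust `"none"` (default, matching a raw correlation-table
#'   presentation) or `"BH"` to add a Benjamini-Hochberg adjusted matrix
#'   `p_adj` computed over the lower triangle.
#' @return An object of class `cor_matrix`: list of K x K matrices `rho`,
#'   `p`, `n` (and `p_adj` if requested), all symmetric with unit diagonal
#'   where defined.
#' @examples
#' m <- cbind(a = 1:6, b = c(2, 4, 5, 7, 9, 12))
#' spearman_matrix(m)$rho
#' @export
spearman_matrix <- function(panel, exact_max = 10,
                            adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  x <- if (inherits(panel, "regular_panel")) panel_matrix(panel)
       else as.matrix(panel)
  K <- ncol(x)
  if (K < 2) stop("need at least 2 variables")
  vars <- colnames(x) %||% paste0("V", seq_len(K))
  rho <- p <- matrix(NA_real_, K, K, dimnames = list(vars, vars))
  n <- matrix(0L, K, K, dimnames = list(vars, vars))
  for (i in seq_len(K)) {
    for (j in seq_len(i)) {
      ok <- !is.na(x[, i]) & !is.na(x[, j])
      nij <- sum(ok)
      n[i, j] <- n[j, i] <- nij
      if (i == j) {
        if (nij >= 2L) rho[i, i] <- 1
        next
      }
      if (nij < 3L) next
      ri <- rank(x[ok, i])
      rj <- rank(x[ok, j])
      if (stats::sd(ri) == 0 || stats::sd(rj) == 0) next
      r <- stats::cor(ri, rj)
      rho[i, j] <- rho[j, i] <- r
      pij <- if (exact_max >= 3 && nij <= exact_max) {
        spearman_perm_pvalue(ri, rj)
      } else if (abs(r) >= 1) {
        0
      } else {
        tt <- r * sqrt((nij - 2) / (1 - r^2))
        2 * stats::pt(-abs(tt), df = nij - 2)
      }
      p[i, j] <- p[j, i] <- pij
    }
  }
  out <- list(rho = rho, p = p, n = n)
  if (adjust == "BH") {
    lt <- lower.tri(p)
    padj <- p
    padj[lt] <- stats::p.adjust(p[lt], method = "BH")
    padj[upper.tri(padj)] <- t(padj)[upper.tri(padj)]
    out$p_adj <- padj
  }
  structure(out, class = "cor_matrix")
}

#' @export
print.cor_matrix <- function(x, digits = 2, ...) {
  K <- nrow(x$rho)
  vars <- rownames(x$rho)
  cat("Pairwise Spearman correlations (rho / p / n), pairwise-complete\n")
  cat("Note: pooled repeated measures; p-values ignore autocorrelation.\n\n")
  for (i in 2:K) {
    cat("** ", vars[i], " **\n", sep = "")
    sub <- seq_len(i - 1L)
    tab <- rbind(rho = round(x$rho[i, sub], digits),
                 p = signif(x$p[i, sub], 2),
                 n = x$n[i, sub])
    colnames(tab) <- vars[sub]
    print(tab)
  }
  invisible(x)
}
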