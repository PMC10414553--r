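---
title: "Modelling single-patient biomarker dynamics with nof1var"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling single-patient biomarker dynamics with nof1var}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nof1var)
```

## The problem and the model

A single intensively monitored patient produces a long, irregular,
incomplete multivariate time series: inflammatory markers (CRP), hepatic
(AP), cardiac (NT-proBNP) and renal (proteinuria) response markers, sampled
when clinical care demanded it. The question — does suppressing
inflammation *forecast* organ recovery, and with what delay? — is a
question about temporal dependence, so it can be answered from one subject.

`nof1var` models the panel as a vector autoregression with exogenous
covariates,

$$X_t = B_1 X_{t-1} + \dots + B_p X_{t-p} + A Z_t + u_t,$$

where $X_t$ stacks the $K$ endogenous markers on a fixed lag grid, $Z_t$
holds at least the regression constant (optionally treatment-pulse
indicators and measurement-gap lengths), and $u_t$ is white noise with
covariance $\Sigma$. Entry $[i, j]$ of $B_\ell$ is the change in marker $i$
expected one grid step after a unit increase in marker $j$, $\ell$ lags
back — the coefficient layout used throughout (rows respond, columns
predict). The key assumptions are linearity of the short-run dynamics,
stationarity over the analysis window (checked via the companion-matrix
spectral radius), and missingness unrelated to the unobserved values
(plausible when gaps stem from visit scheduling).

## From irregular records to a regular panel

Observations are binned into half-open intervals $[k\Delta, (k+1)\Delta)$.
Within a bin the **last** observation of a variable wins: the most recent
laboratory value is the best statement of the patient's state at the end of
the period. $\Delta$ defaults to 6 days, a typical mean spacing for an
intensively monitored patient; it is the unit in which all lags, horizons
and return-to-baseline statements are expressed. Re-gridding at 30–360 days
is the supported way to probe longer lag periods (`sensitivity_suite()`),
rather than inflating $p$, because a 30-day dependence is a *different
sampling* of the same dynamics, not 5 extra free coefficient matrices.

Whether the original analysis binned, interpolated, or used raw dates is
not stated anywhere we could rely on; binning with last-in-bin is this
package's choice and is documented as such.

## Chained-equation imputation with a positivity bound

Estimation requires complete panels. `impute_chained()` produces $M = 20$
of them (default) by chained-equation Monte Carlo. Missing cells are
initialized from each column's observed empirical distribution; then for
`n_iter = 10` sweeps the variables are cycled in column order, and each
variable's missing cells are redrawn from a normal linear regression on the
other variables, **truncated below at 0** so concentrations stay positive.
Two details matter:

* **Parameter uncertainty is propagated** (proper imputation): each sweep
  draws the residual variance from its scaled inverse-$\chi^2$ posterior
  and the coefficients from their normal posterior before drawing cells.
  Without this, Rubin's between-imputation variance underestimates the
  missing-data uncertainty.
* **Truncated draws use inverse-CDF sampling on the upper tail in log
  space**, so a bound far above the conditional mean still returns finite
  draws instead of overflowing — important early in the chain when
  initialized values can be far off.

The conditional models include the **previous-row values of all variables**
by default. This is deliberate and load-bearing: the downstream analysis is
a lag regression, and an imputation model that sees only same-row values is
uncongenial with it — heavily missing columns get rebuilt with no temporal
information, and every cross-lag coefficient that must pass through them is
attenuated toward zero. In simulation at the benchmark's sparsity (22 of
208 proteinuria values observed), same-row-only imputation caps the pooled
AP → proteinuria t-statistic near 1.5 *regardless of the true effect size*,
because the between-imputation noise grows with the signal; adding lagged
covariates restores detection to ~90% of runs. The same-row-only variant
remains available (`lagged_covariates = FALSE`) and is wired into the
sensitivity suite as the "alternative imputation" toggle.

Rank-deficient conditional regressions drop collinear columns with a
warning; columns with fewer than two distinct observed values are a hard
error naming the column, because no regression (and no empirical
initialization worth the name) exists for them.

Convergence is monitored by per-sweep means of the imputed cells;
`check_convergence()` compares the last sweeps against the preceding window
scaled by those sweeps' pooled standard deviation. Because a converged
chain still fluctuates, its drift sits below roughly 2; systematic trend
pushes it well past that (a slope of one window-sd per sweep scores around
5 at the default window).

## Estimation, lag order, pooling

Each equation is ordinary least squares on the lagged states plus $Z_t$ —
identical to the closed-form normal-equations solution, which the test
suite verifies against a brute-force solver on 200 random instances.
Standard errors use the degrees-of-freedom-corrected residual covariance
(divisor $n - Kp - m$); the information criteria use the maximum-likelihood
divisor, the standard econometric convention:

$$\mathrm{AIC} = \ln\det\tilde\Sigma + \frac{2}{n}K(Kp+m),$$

with $\ln n$ (SBIC) and $2\ln\ln n$ (HQIC) as the alternative penalties.
"Bayes–Schwarz" is treated as the single SBIC; HQIC is reported as the
third criterion. `select_lag_order()` drops the first `p_max` rows for
*every* candidate so all criteria are computed on identical estimation
rows; otherwise smaller models would be judged on more data and the
comparison would be biased toward them.

Per-imputation fits are combined by Rubin's rules: pooled estimate = mean;
total variance $T = W + (1 + 1/M)B$ with $W$ the mean squared standard
error and $B$ the between-imputation variance; t-tests use the Rubin
degrees of freedom $(M-1)(1 + W/((1+1/M)B))^2$ (infinite when $B = 0$, the
single-fit residual df when $M = 1$). Pooling t-statistics this way is the
software-standard choice; significance stars follow the clinical-reporting
convention * p<0.10, ** p<0.05, *** p<0.01.

## Impulse responses and their bands

`compute_irf()` propagates a one-time shock through the moving-average
recursion $\Phi_0 = I$, $\Phi_h = \sum_{\ell} B_\ell \Phi_{h-\ell}$. The
default impulse is one residual standard deviation in the shocked
equation; orthogonalized responses use the lower Cholesky factor of
$\Sigma$ under the panel's column order (configurable — with contemporane-
ously correlated shocks, placing the inflammatory marker first is what
produces a period-0 jump in the organ markers). Non-orthogonalized
responses are invariant to variable order; orthogonalized ones are not,
and the package tests both properties. The default horizon is $H = 12$
lag periods (≈ 10 weeks), comfortably past the ~8 periods over which
responses in this setting remain distinguishable from baseline.

Confidence bands come from a residual bootstrap: resample fitted residual
rows, rebuild the series through the fitted recursion from the original
initial rows, refit, recompute the IRF; non-stationary refits are redrawn
(with a cap and a logged count). Two constructions are offered:

* **pointwise** (default): percentile 2.5/97.5 at each horizon — what IRF
  plots conventionally show. Each horizon's band covers at ~95%, but the
  *whole path* stays inside the band noticeably less often, simply because
  twelve 95% events are being intersected.
* **simultaneous** (sup-t): the horizon-wise bootstrap standard deviations
  are scaled by the 95th percentile of the maximum studentized deviation
  over horizons, so the nominal 95% applies to the entire response path.
  Use this when the question is "does this marker respond *at all*
  anywhere in the window" — e.g. for the true-zero CRP → NT-proBNP channel
  in the benchmark, the simultaneous band contains zero everywhere in ~96%
  of simulated datasets.

`return_to_baseline()` reports the first horizon from which the band
contains zero at *every* later horizon up to $H$ — a one-time dip back
through zero does not count as having returned — with `Inf` as the
"never within the window" sentinel.

With an imputation set, bootstrap replicates are spread evenly over the
$M$ completed panels and the point response is the average of the
per-panel responses, so the bands absorb imputation as well as sampling
uncertainty.

## Association tables

`spearman_matrix()` computes pairwise Spearman correlations on
pairwise-complete rows, as rank-then-Pearson (exact under ties, unlike the
$\sum d^2$ shortcut). P-values use the t approximation on $n-2$ df, except
for small pairs ($n \le 10$) where an exact permutation p over all distinct
rank arrangements is computed in compiled code. Pairs with fewer than 3
complete rows, or with a constant member, are reported as not available
rather than raising. No multiplicity adjustment is applied by default,
matching the raw presentation conventional for these tables; a
Benjamini–Hochberg matrix is available behind `adjust = "BH"`. Because the
rows are repeated measures of one subject, these p-values ignore
autocorrelation and overstate evidence; the printed output carries that
warning, and the correlations should be read descriptively.

## The synthetic benchmark: what it emulates, and what it does not

`make_benchmark_case()` freezes the package's validation scenario: $T =
208$ rows at $\Delta = 6$ days (≈ 1240 days of follow-up), four markers
named CRP, AP, NTproBNP, proteinuria, missing-completely-at-random
sparsity tuned to expected observed counts (122, 160, 69, 22), positive
baselines with clip-at-zero positivity, and lag-1 truth

* CRP → CRP 0.70, CRP → AP 1.40, AP → AP 0.46 (echoing the magnitudes a
  published single-patient analysis reports for these channels),
* AP → proteinuria 0.06, proteinuria → proteinuria 0.40,
* NT-proBNP responsive to nothing but itself, and **no** direct
  CRP → proteinuria entry.

The residual scales (4, 10, 150, 0.35) were chosen once so that the full
default pipeline detects the two true channels at the 5% level in roughly
90–100% of runs while keeping the direct CRP → proteinuria coefficient
non-significant — the qualitative pattern the analysis exists to find. The
dependence *magnitudes* are calibration choices, not estimates of any
patient's physiology.

Deliberate simplifications: missingness is MCAR, whereas real gaps cluster
in visit blocks (a block pattern can be imposed manually); shocks are
Gaussian and homoscedastic, with none of the heavy right tails of acute
inflammation; clip-at-zero introduces a mild, intentional violation of the
linear-Gaussian model that the truncated-normal imputer must tolerate; and
there is no measurement-method change, assay drift or dose–response
structure. Passing tests on this generator therefore demonstrates that the
machinery recovers what it assumes — not that any particular clinical
dataset satisfies those assumptions.

## Numerical choices and degenerate inputs

* OLS via QR with pivoting; a rank-deficient design is an error naming the
  collinear columns (for the VAR) or a warning with dropped columns (for
  imputation models, which must keep running inside the chain).
* Residual covariance symmetric by construction; `information_criteria()`
  raises on a singular $\tilde\Sigma$ instead of returning $-\infty$.
* A deterministic panel (zero residuals) is legal: bands collapse onto the
  point IRF and t-values are reported as `NA` where standard errors are 0.
* Ties in ranks are averaged; duplicate `(day, variable)` records are
  rejected at ingestion rather than silently collapsed.
* All Monte Carlo stages derive child seeds from one master seed with a
  fixed integer scheme, so any subset of the pipeline reproduces exactly.

## Problem sizes used by the test suite

The suite exercises the chain at the scales it documents: oracle
equivalence on 200 random small instances; coefficient recovery and
interval coverage on 100 simulated VAR(1) panels of length 1000; lag-order
recovery on 100 VAR(2) panels of length 1000; benchmark chain recovery on
100 pipeline runs at $T = 208$; and band calibration on 100 datasets with
200 bootstrap replicates each. The acceptance script recomputes the same
quantities at 50–60 replicates per block.

## Known limitations

Inference is conditional on the chosen grid step; the pipeline does not
model measurement error in observed cells; MNAR missingness, generalized
(order-invariant) impulse responses, variance decompositions and
cointegration are out of scope; and an n-of-1 fit, however well-calibrated,
describes one patient — hypotheses it generates need confirmation in
larger samples.
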