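---
title: "Testing rank cross-correlations between autocorrelated time series"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing rank cross-correlations between autocorrelated time series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(srdcor)
```

## The problem

Environmental and climatological analyses routinely ask whether two annual
time series — flood peaks and temperatures, discharge and precipitation —
co-vary. Spearman's Rho and Kendall's Tau are the standard dependence
measures here: they are invariant under monotone transforms, depend only on
the copula, and remain defined for heavy-tailed data where the Pearson
correlation may not exist.

The textbook significance tests for these measures assume iid observations.
Real series are autocorrelated, and when *both* series are positively
autocorrelated the sampling variance of the cross-correlation estimators is
inflated: trajectories of two independent but persistent processes
frequently drift in apparent sympathy. Testing such data with the iid
variance produces spurious "significant" correlations at a rate that can be
several times the nominal level. `srdcor` implements the corrected
(*modified*) test, which standardises the rank statistic by an estimate of
the long-run variance, alongside the classical test for comparison.

## Model and test statistics

Let $(X_i, Y_i)_{1 \le i \le n}$ be a sample from a strictly stationary,
absolutely regular ($\beta$-mixing) bivariate process with continuous
margins — short-range dependent data; ARMA, many GARCH, finite moving
averages and suitably mixing Gaussian processes qualify, long-range
dependent processes do not. Under pairwise independence of the two
component processes,

$$\sqrt{n}\,\hat\rho_S \;\xrightarrow{D}\; N\!\big(0,\ \sigma^2\big),
\qquad
\sqrt{n}\,\hat\tau \;\xrightarrow{D}\; N\!\big(0,\ \tfrac{4}{9}\sigma^2\big),$$

with the long-run variance

$$\sigma^2 = 1 + 2\sum_{j > 0} \rho_S^X(j)\,\rho_S^Y(j),$$

where $\rho_S^X(j)$ is the Spearman autocorrelation of $X$ at lag $j$. With
iid data (or when at most one component is autocorrelated) the sum
vanishes and $\sigma^2 = 1$, recovering the classical theory. The Kendall
limit variance is *exactly* $4/9$ of the Spearman one, so one variance
estimate serves both statistics — the implementation asserts this ratio.

The plug-in estimator weights lagged rank autocorrelations with a kernel:

$$\hat\sigma^2 = 1 + 2 \sum_{h=1}^{n-2} \kappa\!\Big(\frac{h}{b_n}\Big)\,
\hat\rho_S^X(h)\, \hat\rho_S^Y(h),$$

and the tests use $T_{\rho_S} = \sqrt{n}\,\hat\rho_S/\sqrt{\hat\sigma^2}$
and $T_\tau = \sqrt{n}\,\hat\tau/\sqrt{(4/9)\hat\sigma^2}$ with standard
normal p-values. The *classical* test replaces $\hat\sigma^2$ by
$n/(n-1)$.

```{r example}
set.seed(1)
d <- simulate_var1(50, phi_x = 0.8, phi_y = 0.8, rho = 0)  # independent pair
tidy(srd_test(d, method = "classical"))
tidy(srd_test(d, method = "modified"))
```

## Tunable parameters

* **Kernel** (`kernel`, default `"quartic"`: $\kappa(t) = (1-t^2)^2$ on
  $[-1,1]$; also `"bartlett"`, or any user function with $\kappa(0)=1$,
  symmetry, $|\kappa|\le 1$ and support in $[-1,1]$). The kernel
  downweights noisy high-lag autocorrelation estimates; with
  compact support, lags beyond $b_n$ contribute nothing.
* **Bandwidth** (`bandwidth`, default $b_n = 3n^{1/4}$, used as a real
  number, not truncated). Larger bandwidths admit more lags: the test
  becomes more conservative under strong autocorrelation, at a cost in
  power — the study harness exposes this trade-off directly
  (`run_rejection_study(..., bandwidth = )`). Data-adaptive bandwidth
  selection is deliberately out of scope. The formal consistency
  conditions on kernel and bandwidth rates are asymptotic and are not
  (cannot be) checked from a single sample; the shipped defaults satisfy
  them, custom choices are the user's responsibility.
* **Lag** (`lag`, default 0): a positive lag pairs $x_i$ with $y_{i+lag}$;
  the test runs on the overlap of length $n - |lag|$, which replaces $n$
  everywhere, including the bandwidth. This convention (rather than, say,
  circular shifting) is ours; the asymptotics carry over to lagged
  cross-correlations.
* **Significance level** (`alpha`, default 0.05) sets the rejection flag
  and the reported critical region on the estimate scale,
  $\pm z_{1-\alpha/2}\sqrt{\hat\sigma^2/n}$.

## Numerical and degenerate-case choices

* **Ties.** The theory assumes continuous margins, so ties occur with
  probability zero. Observed ties get midranks plus a warning (the
  asymptotics are not tie-corrected); a constant series is a hard error.
* **Non-positive variance estimates.** $\hat\sigma^2$ can fall at or below
  zero in adversarial small samples (it is not a quadratic form for
  kernels that do not preserve positive semidefiniteness). It is floored
  at $1/n$ with a warning and a `floored` flag; the floor vanishes
  asymptotically. This is our convention — the formula itself offers none.
* **Autocorrelation normalisation.** $\hat\rho_S^X(h)$ divides the lag-$h$
  rank cross-products by the *full-sample* rank sum of squares, centred at
  the full-sample mean rank. This is the lag-window normalisation whose
  autocorrelation matrices are positive semidefinite.
* **Kendall's Tau** is computed by $O(n\log n)$ inversion counting for
  tie-free data (with an $O(n^2)$ sign-pair fallback under ties); the test
  suite requires exact agreement with full pair enumeration.
* **Classical Kendall variance.** The stated classical convention
  substitutes $n/(n-1)$ for $\hat\sigma^2$; whether the original
  simulations instead used the exact iid variance of $\hat\tau$,
  $2(2n+5)/(9n(n-1))$, is not documented, so we default to the
  substitution and expose the textbook variance via
  `exact_iid_kendall = TRUE`. The two differ negligibly for moderate $n$.
* **Missing values** are rejected, never dropped or interpolated: pairwise
  deletion would silently destroy the serial structure the test depends
  on.

## The simulators and what they emulate

Two generators cover the regimes the test is designed for, and their
defaults are the study conditions used throughout the package's
experiments:

* `simulate_var1(n, phi_x, phi_y, rho)` — bivariate Gaussian VAR(1) with
  diagonal AR matrix and innovation cross-correlation $\rho$ (unit
  innovation variances). It is geometrically $\beta$-mixing; $\phi = 0$
  gives iid pairs. The population Spearman cross-correlation is
  $\rho_S = \frac{6}{\pi}\arcsin(\rho/2)$ (`true_spearman_var1()`),
  since the stationary pairs are bivariate normal with Pearson
  correlation $\rho$ when $\phi_X = \phi_Y$. Paths start from an exact
  draw of the stationary law (component variances $1/(1-\phi^2)$,
  cross-covariance $\rho/(1-\phi_X\phi_Y)$) rather than a burn-in: the
  corollaries assume strict stationarity and the exact start removes a
  tuning knob. A `burn_in` option exists purely for cross-checking.
* `simulate_vma(n, q, nu, rho)` — equal-weight moving average of $2q+1$
  consecutive bivariate-$t_\nu$ innovation pairs ($2q$-dependent, the
  model for smoothed series; $q=0$ is iid). The bivariate $t$ is drawn as
  the elliptical scale mixture $Z\sqrt{\nu/W}$, $W\sim\chi^2_\nu$. For
  null cells the natural choice is `independent_t = TRUE` (two
  independent univariate $t$ series), because the elliptical $\rho = 0$
  case is uncorrelated but not independent. $\nu = 4$ is the default:
  heavy-tailed with finite variance, the setting of the original
  experiments.

Both accept strictly increasing marginal transforms
(`transform_marginals()`), which change nothing rank-based — asserted in
the tests, and useful for emulating non-Gaussian margins.

What the generators do *not* emulate: long-range dependence (excluded by
the theory), regime switches, seasonality within the sampling step, or
measurement error. Passing tests on these generators therefore show
correctness of the method under short-range dependence, not robustness to
violations of it.

## The Monte-Carlo harness

`study_grid()` crosses autocorrelation strength, cross-dependence and
sample size; `run_rejection_study()` simulates each cell and reports
rejection rates with binomial Monte-Carlo standard errors. Two design
choices matter for reproducibility and comparisons:

* every method/measure combination is evaluated on the *same* simulated
  paths (so "classical minus modified" differences carry no extra
  simulation noise, and the shared $\hat\sigma^2$ is computed once);
* each cell derives its seed deterministically from the root seed and the
  cell index, so results do not depend on the order cells run in. R's
  base generator has no counter-based substreams, so the derivation is a
  fixed integer hash; replicates run sequentially within a cell.

The default is 10,000 replicates per cell, matching the original
experiments; the package's own test suite runs the headline null cell
(VAR(1), $\phi = 0.8$, $\rho = 0$, $n = 50$) at full 10,000-replicate
scale and the qualitative grid shapes at 1,000 replicates, with other
distributional properties checked at a few hundred replicates — sizes
chosen to keep the suite fast while leaving Monte-Carlo error well below
the asserted tolerances. In that null cell the classical test rejects at
roughly 31% instead of 5%; the modified test brings this down to roughly
8% at $n = 50$, with the remaining small-sample inflation decaying as $n$
grows (it stems from kernel truncation at $b_n \approx 8$ and the
downward bias of short-sample autocorrelation estimates — a known
behaviour of kernel-HAC corrections under strong persistence).

## The smoothing pipeline

Correlating *smoothed* series is common when the long-term coevolution of
annual data is of interest — and it is exactly the situation the modified
test exists for, because smoothing manufactures autocorrelation.
`moving_average_smooth()` applies a centred equal-weight window (default
5); edge observations without a complete window are dropped rather than
averaged over shrunken windows, so the smoothed series is *exactly* the
equal-weight moving-average process with $q = (\text{window}-1)/2$ (edge
shrinking would make the first and last values differently distributed;
the choice of trimming is ours). `batch_station_test()` smooths and tests
every station of a tidy `station_id, year, a, b` table; stations with
missing values or year gaps are skipped and reported, never interpolated.
No multiplicity correction is applied across stations — the per-station
level is the quantity of interest here, and this mirrors the original
application; users scanning for "any significant station" should adjust
`p_value`s themselves (e.g. `p.adjust`).

`synthetic_station_network()` generates test networks: 51 years per
station by default (a typical annual-series record length), a
configurable fraction of truly dependent stations (VAR(1)-coupled,
$\rho = 0.6$ by default), raw annual values iid by default ($\phi = 0$),
as in classical flood frequency practice. On an all-null network smoothed
with window 5, the classical test flags roughly a third of stations while
the modified test stays near the nominal 5% — the spurious-correlation
phenomenon in miniature, asserted in the test suite.

## Known limitations

* Small-sample inflation of the modified test's type-I error under strong
  bilateral autocorrelation (see above); a larger bandwidth trades this
  against power.
* Power is genuinely lower than the classical test's under autocorrelation;
  that is the price of a correct level, not a defect.
* The $\beta$-mixing assumption is not checkable from data and is not
  checked; long-range dependent inputs silently violate it.
* Confidence intervals under dependence are out of scope (they would need
  a long-run variance estimator valid under pairwise *dependence*).
* Tie-heavy (discrete) data get midranks and a warning, but the null
  distribution is not tie-corrected.
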