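# srdcor

Significance testing of Spearman's Rho and Kendall's Tau
cross-correlations between time series that are **individually
autocorrelated**.

## Why

Rank correlations are the workhorse dependence measures for environmental
and climatological series: invariant under monotone transforms, robust to
heavy tails, copula-based. But the textbook significance tests assume iid
observations. When both series are positively autocorrelated — persistent
hydrological records, or anything passed through a moving-average
smoother — independent series regularly drift in apparent sympathy, and
the iid test declares spurious "significant" correlations far above the
nominal rate.

For strictly stationary, β-mixing (short-range dependent) processes with
continuous margins, under pairwise independence,

    √n ρ̂_S  →  N(0, σ²),      √n τ̂  →  N(0, (4/9) σ²),
    σ² = 1 + 2 Σ_{j>0} ρ_S^X(j) ρ_S^Y(j),

where ρ_S^X(j) is the lag-j Spearman autocorrelation of X. `srdcor`
estimates σ² by kernel-weighting lagged rank autocorrelations,

    σ̂² = 1 + 2 Σ_{h=1}^{n−2} κ(h/bₙ) ρ̂_S^X(h) ρ̂_S^Y(h),

(default: quartic kernel κ(t) = (1−t²)² on [−1,1], bandwidth bₙ = 3n^¼)
and standardises the statistic by it: the **modified test**
T = √n ρ̂_S / √σ̂² holds the nominal type-I error under autocorrelation.
The **classical test** (σ̂² = n/(n−1)) is included for comparison. The
package also provides the two stochastic simulators used to study the
tests (a bivariate Gaussian VAR(1) and an equal-weight vector moving
average with bivariate-t innovations), a Monte-Carlo harness for
type-I-error and power experiments, and a smoothing pipeline for
batch-testing station networks of paired annual series.

For whom: anyone testing cross-correlations between serially dependent
series — hydrologists correlating flood peaks with temperatures,
climatologists working with smoothed indices, or statisticians studying
rank tests under dependence.

## Worked example

Two *independent* AR(1) series with coefficient 0.8, n = 50:

```r
library(srdcor)
d <- simulate_var1(50, phi_x = 0.8, phi_y = 0.8, rho = 0, seed = 42)

srd_test(d, method = "classical")
#> 	Classical rank cross-correlation test (Spearman's Rho)
#>
#> estimate = -0.2833, T = -1.9829, p-value = 0.04738 (two.sided)
#> sigma^2 = 1.0204 (iid-based n/(n-1)), n = 50, lag = 0
#> Reject H0 of pairwise independence at alpha = 0.05

srd_test(d, method = "modified")
#> 	Modified rank cross-correlation test (Spearman's Rho)
#>
#> estimate = -0.2833, T = -1.2872, p-value = 0.198 (two.sided)
#> sigma^2 = 2.4216 (quartic kernel, bandwidth 7.98), n = 50, lag = 0
#> Do not reject H0 of pairwise independence at alpha = 0.05
```

The sample Spearman correlation is −0.28 purely by chance; the classical
test calls it significant (p = 0.047), while the modified test recognises
that for this pair of persistent series an estimate of this size is
unremarkable (σ̂² = 2.42 instead of ≈1, p = 0.198).

At scale, the difference is dramatic. Rejection rates under the null
(2,000 replicates per cell):

```r
g <- study_grid("var1", n = 50, phi = c(0, 0.8), rho = 0)
run_rejection_study(g, reps = 2000, seed = 1)
#>   model   phi  rho     n method    rejection_rate   mc_se
#> 1 var1    0      0    50 classical         0.0455 0.00466
#> 2 var1    0      0    50 modified          0.047  0.00473
#> 3 var1    0.8    0    50 classical         0.314  0.0104
#> 4 var1    0.8    0    50 modified          0.086  0.00627
```

With iid data both tests sit at the nominal 5%. With strong bilateral
autocorrelation the classical test rejects 31% of the time; the modified
test stays near the level (the residual small-sample inflation decays
with n — see the vignette).

Tidy accessors and plots: `tidy()` / `glance()` on test objects,
`autoplot()` on tests (null density with critical region), long-run
variance objects (per-lag contributions) and study results (rejection-rate
curves). A thin CLI lives at `inst/cli/srdcor`
(`srdcor test|simulate|study|batch`).

For smoothed station networks (`batch_station_test()`,
`synthetic_station_network()`): smoothing induces autocorrelation, so on a
network of *independent* pairs the classical test flags a large fraction
of stations while the modified test stays near α — see the vignette.

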