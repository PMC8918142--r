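# survscreen

Feature screening for right-censored survival outcomes with
ultrahigh-dimensional covariates, including network-adjusted screening.

## What this is for

Clinical genomics routinely pairs a few hundred patients (survival time,
possibly censored) with tens of thousands of expression features. Before
any penalized survival model can be fit, the feature space has to be cut
down by *marginal screening*: rank every feature by a cheap association
statistic with the outcome and keep the top few hundred. This package
provides the standard screening utilities for that setting, a
network-adjusted variant that shares signal across a gene–gene dependency
graph, a calibrated survival-data simulator for benchmarking them, and the
metrics used to compare screens.

Observed data per subject are `(V, δ, x)` with `V = min(T, C)`,
`δ = 1{T ≤ C}`, and `x` a p-vector of covariates.

**Screening utilities** (`screen_features()`): marginal Cox partial
likelihood (`pl`), Pearson correlation with log time (`sis`), feature
aberration at survival times (`fast`), Harrell concordance (`cindex`),
censored distance correlation and its composite-quantile variant
(`rcdcs`, `crcdcs`), IPCW Kendall's tau

> τ̂ⱼ = 2/(n(n−1)) Σ_{i<k} [Δ_{ik}/Ĝ(Ṽ_{ik}−)²] · sign(x_{ij}−x_{kj}) · sign(V_i−V_k),

with Ĝ the Kaplan–Meier estimate of the censoring survivor function, and
the network-adjusted `npn_mb`/`mb`: IPCW-tau utilities smoothed by a
PageRank-style update u ← (1−α)|τ̂| + αWu over a sparse graph estimated by
neighborhood selection (lasso regressions, OR rule) on
nonparanormal-transformed (or raw) covariates.

**Simulator** (`sim_scenario()` / `simulate_cohort()`): linear
transformation model H(T) = −x′β + ε with H(t) = log(0.5(e²ᵗ−1)),
extreme-value (PH) or logistic (PO) errors; AR(1), band, hub, cluster and
scale-free covariate networks; sparse linear or nonlinear effects; uniform
censoring calibrated to a target rate; entry-wise t(2) contamination.

**Evaluation** (`run_benchmark()` and friends): minimum model size (MMS),
overlap-coefficient and held-out c-index curves over model sizes, Jaccard
method-similarity, test-set Cox deviance D = −2(ℓ(β̂) − ℓ(0)).

**Application pipeline** (`evaluate_splits()`): repeated random train/test
splits of an expression + clinical dataset, marginal-Cox prefilter,
screening, hard thresholding with grid search, pluggable sparse Cox
fitter, median c-index / deviance / NOSF reporting.

## Worked example

```r
library(survscreen)

sc  <- sim_scenario("sim1", n = 300, p = 200, censoring = 0.3)
coh <- simulate_cohort(sc, seed = 42, calibration_draws = 50000)
coh
#> Simulated survival cohort (sim1, ar1 structure)
#>   n = 300 subjects, p = 200 features
#>   events: 208 (censoring rate 30.7%)
#>   true predictors: 14; contaminated entries: 9.89%
#>   censoring: U(0, 2.79)

rk <- screen_features(coh, method = "npn_mb")
rk
#> Feature ranking (npn_mb): 200 features
#>   top: f25 (0.237), f24 (0.198), f15 (0.1907), f14 (0.1881), f21 (0.18)

mms(rk, coh$truth)
#> [1] 95
mms(screen_features(coh, method = "ipcw_tau"), coh$truth)
#> [1] 192
overlap_coefficient(top_features(rk, 50), coh$truth)
#> [1] 0.8571429
```

The cohort draws 300 subjects with AR(1)-correlated features, 14 of which
truly drive survival; censoring is calibrated to 30% and one entry in ten
is replaced by a heavy-tailed outlier. The network-adjusted screen needs
95 features to cover all 14 true predictors where the plain IPCW-tau
ranking needs 192, and 12 of the 14 (overlap 0.857) already sit in its top
50 — the smoothing over the estimated feature graph is what closes that
gap. `run_benchmark()` repeats this comparison over replications;
`plot()` methods draw the MMS distributions and metric curves.

A command-line front end for the same operations
(`simulate` / `screen` / `benchmark` / `predict` subcommands) is installed
at `inst/cli/survscreen.R`.

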