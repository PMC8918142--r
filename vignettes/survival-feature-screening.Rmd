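---
title: "Feature screening for censored survival outcomes: models, utilities and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Feature screening for censored survival outcomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(survscreen)
```

## The problem

With tens of thousands of expression features and a few hundred patients,
fitting a multivariable survival model directly is hopeless; the standard
two-step strategy first *screens* features by a cheap marginal utility,
keeps a few hundred top-ranked candidates, and only then runs penalized
model selection. This package implements a family of such screening
utilities for right-censored outcomes, a network-adjusted variant that
borrows strength across a gene-gene dependency graph, a transformation-model
simulator for benchmarking them, and the surrounding evaluation machinery.

Throughout, the observed data per subject are `(V, delta, x)` with
`V = min(T, C)` the observed time, `delta = 1{T <= C}` the event indicator,
and `x` a p-vector of covariates.

## The generative model of the simulator

Survival times follow the linear transformation model

$$H(T_i) = -x_i'\beta_0 + \epsilon_i, \qquad
  H(t) = \log\!\big(0.5\,(e^{2t} - 1)\big),$$

with a standard extreme-value error (CDF $1 - \exp(-e^u)$, the log of a
unit exponential) giving a proportional-hazards model, or a standard
logistic error giving proportional odds. `tm_inverse()` is the analytic
inverse $H^{-1}(u) = 0.5\log(1 + 2e^u)$, so with $\eta = 0$ the PH baseline
survivor function is $S(t) = \exp(-0.5(e^{2t}-1))$ (median
$0.5\log(1 + 2\log 2) \approx 0.4349$) and the PO one is
$(1 + 0.5(e^{2t}-1))^{-1}$ (median $0.5\log 3 \approx 0.5493$). These
closed forms anchor the simulator's tests.

Three built-in designs (`sim_scenario()`), all with n = 500 subjects and
p = 2,000 features by default:

* **sim1** — AR(1) correlation $0.5^{|j-k|}$; a sparse coefficient vector
  with 14 nonzero entries among the first 25 coordinates; linear links.
* **sim2** — the same coefficients, but features 1, 2, 4 and 5 act through
  $|x|$, $|x|$, $x^2$ and $1(x>0)$: signals invisible to linear
  correlation screens.
* **sim3** — graph-structured covariates (band, hub, cluster or scale-free)
  with a $\pm 1.5$ coefficient vector (15 nonzero entries as printed).

For the graph structures the covariance is built the way graphical-model
benchmark generators do it: a 0/1 adjacency $A$ per structure, precision
$\Omega = vA + (|\lambda_{\min}(vA)| + 0.1 + u)I$, covariance
$\Omega^{-1}$ rescaled to unit diagonal. Defaults $v = 0.3$, $u = 0.1$,
hub/cluster group size 20, cluster edge probability 0.3, and one edge per
node for preferential attachment are conventional generator settings; the
designs only fix the structure family, so these are package choices,
exposed as arguments.

**Censoring.** Censoring times are U(0, b) with b calibrated by
`calibrate_censoring()` to hit a target rate (30/50/70% are the study
settings). One Monte-Carlo sample of latent times T (200,000 draws by
default) is taken; because C is uniform and independent of T, the
censoring rate at bound b is exactly `mean(pmin(T, b))/b` on that sample —
a smooth, strictly decreasing function of b — so bisection converges
deterministically. Tolerance 0.005 on the rate. Validation on independent
cohorts of 100,000 reproduces the targets within one percentage point.

**Contamination.** With probability 0.1 an entry of the covariate table is
replaced by an independent t(2) draw (`contaminate()`). The granularity
(entry versus whole subject) is a genuine open choice; entry-level
replacement matches the heavy-tailed marginal-contamination convention of
the robust-screening literature and is the default, with a subject-level
mode behind `unit = "subject"`. Contamination is treated as *measurement*
corruption: the linear predictor and hence the survival times are computed
from the clean covariates, and only the table handed to the screeners is
contaminated. The flag `contaminate_before_eta` flips this for users who
want contamination to propagate into the outcome.

## The screening utilities

All utilities are non-negative, and all rankings break ties by ascending
feature index so results are deterministic.

* **pl** — maximized marginal Cox partial likelihood, reported as
  $\ell_j(\hat\beta_j) - \ell_j(0)$ (Breslow ties). The shared
  $\ell_j(0)$ makes this equivalent, as a ranking, to the raw maximum.
* **sis** — $|\mathrm{cor}(x_j, \log V)|$. Log time because survival times
  are positively skewed; the raw-time mode is a flag. Censoring is ignored
  by construction — this is the naive baseline.
* **fast** — with $x_j$ standardized,
  $|n^{-1}\sum_{i:\delta_i=1}(x_{ij} - \bar x_j(V_i))|$, where
  $\bar x_j(t)$ is the mean over the at-risk set $\{k: V_k \ge t\}$ — a
  score-type aberration statistic.
* **cindex** — $|C_j - 0.5|$ with $C_j$ Harrell's concordance of $x_j$ as a
  risk score, so protective and hazardous features rank symmetrically.
* **ipcw_tau** — inverse probability-of-censoring weighted Kendall tau:
  pairs are usable when the earlier observed time is an event, weighted by
  $\hat G(\tilde V_{ik}-)^{-2}$ where $\hat G$ is the Kaplan-Meier
  estimate of the censoring survivor function. With no censoring it *is*
  classical Kendall tau (verified to 1e-12 against brute-force pair
  counting). Weights are capped at $1/0.05^2$ — below a $\hat G$ of 0.05
  single pairs would otherwise dominate the sum — and the cap is reported
  when it binds.
* **rcdcs / crcdcs** — distance correlation after replacing $x_j$ by its
  ECDF and V by the Kaplan-Meier CDF of T (rcdcs); the composite variant
  (crcdcs) averages, over the quantile grid {0.25, 0.5, 0.75}, weighted
  distance correlations between the $x_j$-ECDF and the indicator of
  surviving past the KM quantile, with redistribute-to-the-right weights
  $\delta_i/\hat G(V_i-)$. The exact composite construction is only
  sketched in the literature this follows; the form here (IPCW weights on
  events, quantiles above the KM plateau dropped with a warning) is the
  package's stated default and is exercised by a no-censoring reduction
  test where it collapses to a plain distance correlation of ranks.

The censoring KM uses the convention that at tied times deaths precede
censorings in the risk-set bookkeeping, which is what makes
$\hat G(V-)$-weighting consistent; it is implemented directly rather than
by label-swapping a standard KM fit, whose tie convention differs.

## Network-adjusted screening (NPN-MB and MB)

Marginal utilities ignore that co-regulated genes carry correlated signal.
The network-adjusted screen:

1. **Nonparanormal transform** (`npn_transform()`): per column, Winsorized
   ECDF $\tilde F = \mathrm{clamp}(r/(n+1), \delta_n, 1-\delta_n)$ with
   $\delta_n = 1/(4 n^{1/4}\sqrt{\pi \log n})$, then $\Phi^{-1}$. Ranks are
   preserved; marginals become Gaussian, so step 2's Gaussian
   graphical-model machinery applies to contaminated, heavy-tailed data.
   The MB variant skips this step and uses the raw covariates — the
   package's own Monte-Carlo tests show the transform buys strictly better
   graph recovery under t(2) contamination.
2. **Neighborhood selection** (`mb_graph()`): lasso regression of each
   standardized column on the rest; edge (j,k) under the OR rule when
   either direction is nonzero (the more sensitive rule; AND available).
   Default penalty $\lambda = c\sqrt{\log p / n}$ with $c = 2$: under the
   null, entry of a spurious neighbor requires a sample correlation of
   about $3.5/\sqrt n$, so false edges are rare, while AR(1)-strength
   partial correlations (0.4 at $\rho = 0.5$) still enter comfortably.
   With $c = 1$ the threshold sits near $1.7$ null standard errors and
   independent blocks acquire dozens of spurious edges — measurably worse
   in the two-block recovery test — so the larger constant ships as the
   default and `lambda_c`/`lambda` remain user-settable.
3. **Random-walk smoothing** (`adjust_utilities()`): a PageRank-style
   Markov update $u \leftarrow (1-\alpha)|\tau| + \alpha W u$ with $W$ the
   row-stochastic walk matrix (isolated features get self-loops so mass is
   conserved). The exact published adjustment statistic is not printed in
   the sources this follows; the one-step convex combination with
   $\alpha = 0.5$ is the simplest construction consistent with a Markov
   smoothing, and both $\alpha$ and the iteration count are exposed and
   recorded in the ranking's diagnostics.

Graph estimation is the pipeline's cost bottleneck at p = 2,000; a
`pre_cap` option estimates the graph on the top-K features by raw utility
only, leaving the rest isolated, for desk-scale runs.

## Evaluation machinery

* **MMS** (`mms()`): the maximum rank of any true feature — the smallest
  model covering the truth. Reported as full replication samples so the
  distribution (not just percentiles) can be summarized.
* **Overlap coefficient** $|A\cap B|/\min(|A|,|B|)$ against the truth over
  a model-size grid, and **Jaccard** $|A\cap B|/|A\cup B|$ between methods
  at model size 500 (`method_similarity()`).
* **Harrell's C** (`harrell_c()`, via `survival::concordance` in
  risk-score orientation, cross-checked against brute-force pair counting)
  and test-set **deviance** $D = -2(\ell(\hat\beta) - \ell(0))$ with
  $\ell$ the Breslow log partial likelihood evaluated at fixed
  coefficients (`cox_pll()`; at $\beta = 0$ it reduces to
  $-\sum_{events}\log(\text{risk-set size})$, the identity its tests pin).
  Negative deviance means the fitted model beats the null on held-out data.
* **`run_benchmark()`** drives replications: per replication a fresh
  cohort (seed = master + counter), every requested method, MMS and curve
  bookkeeping; for c-index curves a 1:1 split with a ridge-stabilized Cox
  refit (penalty 1e-4) on the top-k training features, scored on the
  held-out half by default (an in-sample mode exists because published
  curve protocols often leave this unstated). Replications failing for
  numerical reasons are logged and skipped; more than 10% failures aborts.

The study scale is 200 replications at p = 2,000. The package's own tests
run the ordering comparison (network-adjusted versus plain IPCW tau) at
n = 400, p = 500 with 20 replications per structure — the scale at which
the qualitative conclusion is already stable and a full test run stays
comfortably interactive — and the benchmark accepts `replications`/`p` up
to full scale.

## The application pipeline

`evaluate_splits()` reproduces the real-data protocol: repeated random
train/test splits (default 5 at a 4:1 ratio; 368 samples split 294:74),
marginal-Cox prefilter to 2,000 features, screening, hard thresholding at
a size chosen by grid search over 10–300, a penalized Cox fit via a
pluggable fitter, and median test-set c-index, deviance and NOSF across
splits. Two deliberate departures from common practice are configurable:

* Prefiltering happens *inside* the training folds by default, because a
  whole-data prefilter leaks test information into feature selection;
  `paper_protocol = TRUE` restores the whole-data variant for
  comparability with published analyses that prefilter first.
* The grid-search criterion is the median held-out c-index — "best overall
  prediction performance" admits several readings, and this one is
  monotone, robust across splits, and recorded in the report.

The MCP-penalized fitter used in published analyses is deliberately out of
scope: `fitter_mcp()` is an adapter slot taking any
`function(x, time, status) -> coefficients`, and the shipped default is a
ridge-stabilized Cox fit (`fitter_ridge()`). NOSF counts coefficients
above 1e-8 in magnitude — meaningful sparsity therefore comes from the
fitter, and with the ridge fallback NOSF typically equals the threshold
size.

## Numerical choices and degenerate inputs

* Constant columns get utility 0 (with a warning where the estimator is
  otherwise undefined) rather than an error, so screens never die on one
  dead probe.
* Rank ECDFs use average ranks over n; KM quantiles are leftmost times
  whose CDF reaches q.
* Tied observed times contribute zero to tau-type pair sums; Breslow
  handling everywhere a partial likelihood appears.
* `tm_inverse()` switches to the asymptotic branch
  $u/2 + \log(2 + e^{-u})/2$ for positive u so it cannot overflow.
* All simulator randomness is seed-addressable; cohorts, benchmarks and
  split reports are exactly reproducible from `(config, seed)`.

## What the simulator does and does not emulate

The synthetic cohorts have Gaussian (or contaminated-Gaussian) covariates
with exactly known sparse effects, uniform censoring independent of
covariates, and no missingness. Real expression data have skewed,
batch-affected, dependently censored measurements and correlated effect
clusters of unknown size. Passing the package's tests therefore
demonstrates correctness of the estimators and the claimed *relative*
behavior of the methods under the stated designs — not that any method
will achieve a particular accuracy on a given clinical cohort.

## Known limitations

* No competing risks, time-varying covariates, or non-uniform censoring
  families in the simulator.
* No iterative (ISIS-style) or p-value-thresholded screening — hard top-d
  thresholding only, as in the protocol this implements.
* The network adjustment uses one fixed graph per data set; no stability
  selection across penalties, and no directed or pathway-informed graphs.
* Distance-correlation screens are O(n²) per feature; at n in the
  thousands prefer the tau- or score-based utilities.
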