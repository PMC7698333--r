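---
title: "Nonparametric limits of agreement: estimators, coverage, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Nonparametric limits of agreement: estimators, coverage, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nploa)
```

## The problem

A method-comparison study measures the same quantity on each subject with two
instruments or protocols and asks how well they agree.  The standard summary
is the pair of Bland–Altman limits of agreement (LoA): the interval expected
to contain 95% of the paired differences $d_i = m_{1i} - m_{2i}$.  The
classical limits,

$$\bar d \pm 1.96\, s_d,$$

with $\bar d$ the mean difference (the *bias*) and $s_d$ the sample standard
deviation, are valid as a 95% population interval only when the differences
are normally distributed with constant bias and variance over the measurement
range.  When a log transformation or a regression model of the bias cannot
rescue those assumptions, the limits must be estimated as the 2.5% and 97.5%
quantiles of the differences directly — a hard problem, because both targets
are extreme tail quantiles and method-comparison samples are small.

This package implements six nonparametric estimators of those tail
quantiles, the classical limits as a benchmark, percentile-bootstrap
confidence intervals for the limits, and a Monte-Carlo engine that measures
how reliably each estimator's limits cover 95% of the population across a
panel of reference distributions.

## The estimators

All six are *L-statistics*: linear combinations
$\hat Q(p) = \sum_{i=1}^n W_i\, X_{(i)}$ of the order statistics
$X_{(1)} \le \dots \le X_{(n)}$ of the differences, with weights that depend
only on $(n, p)$.  `estimator_weights(id, n, p)` exposes every weight vector;
each one sums to 1, so every estimator is a weighted average and is exactly
location–scale equivariant (both properties are enforced by tests).

* **`sq` — sample quantile.**  With $h = p(n+1)$, $r = \lfloor h \rfloor$ and
  $\alpha = h - r$,
  $\hat Q = (1-\alpha) X_{(r)} + \alpha X_{(r+1)}$.
  Only the two order statistics flanking the target rank get weight.  The
  estimator requires $1 \le p(n+1) \le n$; at the LoA levels
  $p \in \{0.025, 0.975\}$ this means $n \ge 39$.  (Study-size folklore
  rounds this to "at least 40 subjects"; the formula itself is well defined
  at $n = 39$, and `min_sample_size("sq")` returns 39.)
* **`hd` — Harrell–Davis.**  $W_i = I_{i/n}(a, b) - I_{(i-1)/n}(a, b)$ with
  $a = p(n+1)$, $b = (1-p)(n+1)$ and $I_x(a,b)$ the *regularized* incomplete
  beta function (the Beta CDF).  The regularized form is essential: it makes
  the weights telescope to exactly 1.  Every observation receives weight.
* **`bp` — Bernstein polynomial.**  $W_i = B(i-1;\, n-1,\, p)$, the binomial
  pmf; weights sum to 1 by normalization of the pmf.
* **`hdlc` — Harrell–Davis on a level-crossing empirical distribution.**
  As `hd`, but the Beta CDF is evaluated at the cumulative sums $q_i$ of
  unequal observation weights
  $w_1 = w_n = \tfrac12\bigl(1 - \tfrac{n-2}{\sqrt{n(n-1)}}\bigr)$,
  $w_j = 1/\sqrt{n(n-1)}$ for $1 < j < n$.  This is the unique reading of
  the level-crossing weights under which $\sum_j w_j = 1$ exactly (the
  algebraic identity $2w_1 + (n-2)w_{\text{int}} = 1$), which we adopt and
  verify by test.
* **`sv` — Sfakianakis–Verginis (first form).**  Averaged adjacent binomial
  probabilities $\tfrac12(B(i) + B(i-1))$ on the interior, with boundary
  corrections on $X_{(1)}, X_{(2)}, X_{(3)}$ and
  $X_{(n-2)}, X_{(n-1)}, X_{(n)}$ designed to improve tail estimation in
  small samples.  Requires $n \ge 5$ so the two boundary groups are disjoint.
* **`no` — Navruz–Özdemir.**  Binomial-probability weights
  $B(i)(1-p) + B(i+1)p$ on the interior with a different boundary
  correction; also $n \ge 5$.  The trailing boundary terms are the exact
  mirror image (under $p \to 1-p$, $i \to n+1-i$) of the leading ones, so
  the estimator satisfies $\hat Q_p(X) = -\hat Q_{1-p}(-X)$; our tests check
  the implementation against an independent term-by-term transcription of
  the defining expression.

The $n \ge 5$ floor for `sv` and `no` is our choice: below it the boundary
index groups overlap and the defining expressions double-weight
observations ambiguously.

Binomial pmfs come from `dbinom()`, which computes on the log scale
internally; weights remain finite and normalized up to $n = 1000$ at
$p = 0.025/0.975$ (tested).

## Reference distributions and the coverage study

`study_distributions()` returns the six-member panel used to stress-test the
estimators: standard normal, lognormal (sdlog 1), Beta(2,5), Beta(2,2),
chi-squared(4), and exponential(1) — symmetric, skewed, bounded and
heavy-tailed shapes.  Each member carries an exact sampler, CDF and quantile
function, so the quality of a pair of estimated limits $(\ell, u)$ on a
sample from $F$ can be scored exactly as the *coverage probability*

$$c = F(u) - F(\ell),$$

the population mass the interval actually captures (nominal value 0.95).
`run_scenario()` simulates one (distribution, $n$, estimator) cell:
`replicates` independent samples, one pair of limits each, one coverage value
each.  `run_study()` orchestrates the full grid and produces per-cell
summaries, worst-case tables and boxplot statistics.

Design choices that matter:

* **Lognormal parametrization.**  The log-mean of the lognormal member is
  configurable (`lognormal_meanlog`, default 0).  Coverage results are
  invariant to it — all estimators are location–scale equivariant on the
  sampled values and the coverage statistic transforms along — but absolute
  error summaries scale by $e^{\mu_{\log}}$, so the choice is exposed rather
  than hidden.
* **Crossed limits.**  No estimator guarantees $\ell \le u$ on pathological
  samples.  `estimate_loa()` warns and returns the pair as computed;
  `coverage()` clamps $F(u) - F(\ell)$ at 0, because a negative value has no
  probability interpretation.  Occurrences are counted per cell
  (`n_crossed`) and surfaced by `run_study()`.  None occur on the reference
  grid at $n \ge 50$.
* **Summary quantiles.**  Coverage distributions are summarised by their 5%
  quantile, quartiles, median and mean; quantiles use linear interpolation
  of order statistics (`stats::quantile()` type 7, R's default).
* **Seeding.**  Every cell derives its own RNG substream from a 31-bit hash
  of (seed, distribution, $n$, estimator), so results are independent of the
  order cells are run in and identical configurations reproduce output CSVs
  byte-for-byte; the caller's RNG state is left untouched.  Within a cell
  the replicate draws come from one vectorised stream in fixed order.
* **Undefined cells.**  A cell whose $n$ is below the estimator's minimum is
  skipped with a logged reason rather than silently dropped — e.g. `sq` at
  $n < 39$.

## Error summaries: RMSE and MAE

For each cell the engine also scores the per-replicate tail-quantile
estimates against the exact distribution quantiles, with two summaries:
root-mean-squared error (`rmse()`) and mean absolute error (`mae()`).  Both
are reported because tail-estimate error distributions are markedly skewed:
for approximately normal errors MAE $\approx 0.8\,$RMSE, and the gap widens
with heavy tails, so the two are *not* interchangeable and published error
figures for such estimators can be on either scale.  MAE is the less
outlier-sensitive summary; RMSE penalises occasional large misses.  For the
classical benchmark the "quantile estimate" scored is the corresponding
parametric limit $\bar d \mp 1.96 s_d$.

## Bootstrap confidence intervals

`bootstrap_loa_ci()` supplements the limits with percentile-bootstrap
intervals: resample the differences with replacement, recompute both limits,
take the empirical $\alpha/2$ and $1-\alpha/2$ quantiles of each limit
separately.  The percentile method is the minimal defensible choice given no
stronger prescription; defaults are 2000 resamples and a 95% level, both
configurable.  Results are deterministic given `seed`.  Our outer
Monte-Carlo check (200 studies of $n = 100$ normal data) finds the lower-limit
interval covering the true quantile at roughly the nominal rate.

## What the synthetic-data generator does and does not emulate

`generate_fixture()` and the simulation engine draw paired differences i.i.d.
from a known distribution; the paired-data fixture adds them to a common
underlying value so that $m_1 - m_2$ follows the chosen distribution exactly.
This emulates the core difficulty — estimating extreme tail quantiles of
non-normal differences from small samples — but deliberately not:

* non-constant bias or variance across the measurement range (the case where
  regression/transformation approaches, out of scope here, apply);
* rounding, ties and detection limits of real instruments;
* within-subject replicates or any dependence between pairs.

Passing tests therefore demonstrate correctness of the estimators and the
study machinery under the stated sampling model, not robustness to those
real-data features.

## Problem sizes used by the test suite

The reproduction checks run the study cells at full fidelity (5000
replicates per cell, $n = 50$ and $n = 1000$).  The large-$n$ convergence
check (mean coverage within 0.01 of 0.95 at $n = 1000$ for every
nonparametric estimator × distribution) uses 400 replicates per cell, which
bounds the Monte-Carlo standard error of the mean coverage well below the
0.01 margin; the consistency property (error decreasing over
$n \in \{50, 200, 1000\}$) uses 500 replicates.  The classical limits are
included in the convergence check only under normality: under the other
panel members $\bar d \pm 1.96 s_d$ converges to
$F(\mu + 1.96\sigma) - F(\mu - 1.96\sigma) \ne 0.95$, which is precisely the
inappropriateness the benchmark is meant to display.

## Known limitations

* The `sv` and `no` boundary corrections place small negative weights on a
  few order statistics; on bounded distributions their estimates can fall
  slightly outside the observed range in small samples.
* The classical limits are reported without finite-sample refinements
  (no $t$-quantile multiplier); the multiplier is the conventional fixed
  1.96.
* Coverage clamping at 0 discards the magnitude of a crossed pair; only the
  count is retained.
* The config loader accepts the six panel distributions by name; arbitrary
  user distributions can be passed programmatically as `dist_spec` objects
  but are untested territory.
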