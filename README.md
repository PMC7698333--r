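# nploa — nonparametric limits of agreement

Tools for method-comparison studies on quantitative outcomes when the paired
differences cannot be assumed normal.  A Bland–Altman analysis summarises
agreement between two measurement methods by the *limits of agreement*
(LoA): the interval expected to contain 95% of paired differences,
classically `mean ± 1.96 · sd`.  When normality fails and neither a
transformation nor a regression model of the bias applies, the limits must
be estimated as the 2.5% and 97.5% quantiles of the differences
nonparametrically — extreme tail quantiles, from the small samples typical
of method comparison.

The package provides:

* **Six L-statistic tail-quantile estimators** `Q̂(p) = Σ Wᵢ X₍ᵢ₎` over the
  order statistics, differing in their weight construction:
  sample quantile (`sq`, two flanking order statistics at rank `p(n+1)`),
  Harrell–Davis (`hd`, regularized-incomplete-beta increments),
  Bernstein polynomial (`bp`, binomial pmf `B(i−1; n−1, p)`),
  Harrell–Davis on a level-crossing empirical distribution (`hdlc`),
  Sfakianakis–Verginis (`sv`) and Navruz–Özdemir (`no`, both
  boundary-corrected binomial weights).
* **Classical limits** (`ba_loa()`) as the parametric benchmark, and
  **percentile-bootstrap confidence intervals** for any limit pair
  (`bootstrap_loa_ci()`).
* A **Monte-Carlo engine** (`run_scenario()`, `run_study()`) scoring each
  estimator's limits by exact coverage probability `F(upper) − F(lower)`
  across six reference distributions (normal, lognormal, Beta(2,5),
  Beta(2,2), chi-squared(4), exponential(1)), with RMSE/MAE of the tail
  estimates against exact quantiles.
* A small **CLI** (`loa_cli()`, wrapper in `inst/cli/nploa.R`) with
  `estimate-loa`, `run-study` and `make-fixture` subcommands.

## Worked example

```r
library(nploa)

# synthetic method-comparison data: 75 pairs whose differences are chi-squared(4)
f <- tempfile(fileext = ".csv")
generate_fixture("paired-data", "chisq_4", n = 75, seed = 42, file = f)
pd <- read_paired_data(f)
pd
#> <paired_data> n = 75 pairs (0 dropped); bias 4.145, sd of differences 3.074

ba_loa(pd)            # classical limits -- misleading here (skewed differences)
#> Limits of agreement (BA, n = 75)
#>   bias : 4.14474
#>   lower: -1.88029
#>   upper: 10.1698

bootstrap_loa_ci(pd, "hd", n_boot = 2000, seed = 1)
#> Limits of agreement (HD, n = 75)
#>   lower: 0.397294
#>   upper: 13.2284
#>   95% percentile bootstrap (2000 resamples, seed 1):
#>     lower limit CI: [0.171695, 0.850682]
#>     upper limit CI: [8.83534, 15.73]
```

The classical lower limit is negative although chi-squared differences are
strictly positive (its true 2.5% quantile is 0.484); the Harrell–Davis
limits respect the skewness.

Coverage of an estimator under a known distribution:

```r
res <- run_scenario("exp_1", 50, "sq", replicates = 5000, seed = 1)
res
#> <scenario_result> exp_1, n = 50, SQ, 5000 replicates
#>   coverage: mean 0.9525, median 0.9578, q25 0.9382, q05 0.9002
```

So with n = 50 exponential differences, the sample-quantile limits capture
on average 95.3% of the population, and in 95% of studies at least 90% —
the kind of statement the full study grid
(`run_study(study_config(...))`, config template in
`inst/extdata/reference_study.yaml`) tabulates for every estimator,
distribution and sample size.

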