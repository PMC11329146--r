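# huntcast

Counterfactual trend modelling and anomaly detection for annual
hunting-license count panels.

## The problem

Recreational hunting in Northern Italy has been declining for decades, and
the provinces hit earliest and hardest by the COVID-19 epidemic appeared to
lose disproportionately many hunters in the 2020/2021 and 2021/2022 seasons.
Establishing that requires a counterfactual: how many licenses *would* each
province have issued had the 2011–2019 trend simply continued? `huntcast`
implements that analysis as a reusable, tested pipeline for anyone working
with administrative count panels (wildlife agencies, epidemiologists,
ecologists studying participation trends):

1. **Trend model.** Annual license counts `y[p,t]` for province `p` in year
   `t` follow a negative binomial, `y[p,t] ~ NB(mu[p,t], theta)` with
   `Var = mu + mu^2/theta`, and

   ```
   log mu[p,t] = alpha + u[r(p)] + v[p] + beta * (t - t0) + gamma[t]
   ```

   with region intercepts `u`, province intercepts `v` nested in regions, a
   log-linear year trend `beta`, and a shared first-order random-walk year
   effect `gamma` (anchored at `gamma[t0] = 0`). Posterior sampling is by an
   adaptive Metropolis-within-Gibbs sampler written in C++, with slice
   updates for the variance components and exchange moves along the weakly
   identified ridges; split-Rhat and effective-sample-size diagnostics flag
   any non-converged fit.
2. **Model selection.** Candidate structures (linear only, random walk only,
   both, region-only vs nested intercepts) are ranked by leave-one-out
   expected log predictive density, estimated by Pareto-smoothed importance
   sampling with an automatic exact-refit fallback.
3. **Counterfactual prediction.** For post-period seasons the random walk is
   extended by forward simulation and a full posterior-predictive count
   distribution is drawn per province; its median and central 95% interval
   are the counterfactual summary.
4. **Anomaly detection.** An observed count strictly below the 2.5% bound is
   an anomalous decrease. Deficits are quantified against the predictive
   median and against both interval bounds (a min–max range), and summed
   over flagged provinces per region.
5. **Association.** Tie-aware Spearman rank correlation (midranks + Pearson
   on ranks) between the absolute deficits and a provincial excess-mortality
   covariate — the percentage increase of a year's deaths over the 2015–2019
   mean — including lagged pairings.
6. **Synthetic data.** A generator with the exact generative structure above
   plus injected post-period drops coupled to a simulated mortality
   covariate, with full ground truth, so every stage is testable without the
   original registries.

## Worked example

The package bundles the published reference table of observed counts and
counterfactual predictions for the 29 flagged Northern-Italy
province-seasons. Feeding those inputs through the anomaly operations:

```r
library(huntcast)

rec <- reference_anomaly_records(2020)
rec[rec$province == "Milan", c("observed", "pred_median", "pred_lo",
                               "pred_hi", "delta_median", "delta_lo",
                               "delta_hi", "pct_median")]
#>   observed pred_median pred_lo pred_hi delta_median delta_lo delta_hi pct_median
#> 1     5067        5640    5463    5823          573      396      756      -10.2

aggregate_region(rec)[, c("region", "n_flagged", "deficit_median",
                          "deficit_lo", "deficit_hi")]
#>           region n_flagged deficit_median deficit_lo deficit_hi
#> 1 Emilia-Romagna         5            808        255       1382
#> 2       Lombardy         7           2720       1788       3688
#> 3        Tuscany         2            538        259        828
```

Milan issued 5,067 licenses in the 2020/2021 season against a predicted
5,640 (95% interval 5,463–5,823): 573 fewer than the most likely
counterfactual, plausibly between 396 and 756 fewer. Lombardy as a whole
lost 2,720 licenses across its seven flagged provinces. Deficit size
rank-correlates with provincial excess mortality:

```r
ref <- reference_anomalies()
cov <- data.frame(province = ref$province[ref$year == 2020], year = 2020,
                  excess_mortality_pct = ref$excess_mortality_pct[ref$year == 2020])
associate_anomalies(rec, cov, 2020)
#> <association_result> anomalies 2020 vs excess mortality 2020 (flagged provinces, n = 14)
#>   Spearman rho = 0.524
```

The full simulate → select → fit → predict → detect → associate sequence on
synthetic data lives in the numbered scripts under `analysis/`
(`Rscript analysis/01_simulate.R` and onwards, writing to `results/`), or as
a single call via `run_pipeline(pipeline_config(...))`.

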