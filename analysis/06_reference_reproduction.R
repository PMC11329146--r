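#!/usr/bin/env Rscript

# Stage 6 — reproduce the published worked example.
#
# The bundled reference table carries the observed counts, counterfactual
# predictions and excess-mortality percentages for the 29 Northern-Italy
# province-seasons reported as anomalous decreases. Feeding those inputs
# through the same flagging, aggregation and association operations used on
# synthetic data must return the published deficits and the published 2020
# rank correlation of 0.52.

suppressPackageStartupMessages(library(huntcast))

ref <- reference_anomalies()
for (yr in c(2020, 2021)) {
  rec <- reference_anomaly_records(yr)
  agg <- aggregate_region(rec)
  message(sprintf("season %d: %d flagged provinces", yr, nrow(rec)))
  for (i in seq_len(nrow(agg))) {
    with(agg[i, ], message(sprintf("  %s: %0.f fewer (%0.f-%0.f)",
                                   region, deficit_median, deficit_lo,
                                   deficit_hi)))
  }
  cov <- data.frame(province = ref$province[ref$year == yr], year = yr,
                    excess_mortality_pct = ref$excess_mortality_pct[ref$year == yr])
  res <- associate_anomalies(rec, cov, yr)
  message(sprintf("  deficit vs excess mortality: Spearman rho = %.2f (n = %d)",
                  res$rho, res$n))
}

dir.create("results", showWarnings = FALSE)
write.csv(rbind(reference_anomaly_records(2020), reference_anomaly_records(2021)),
          "results/reference_reproduction.csv", row.names = FALSE, quote = FALSE)
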