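#!/usr/bin/env Rscript

# Stage 4 — flag anomalies and aggregate by region.
#
# A province-season is an anomalous decrease when its observed count falls
# strictly below the 2.5% bound of its counterfactual distribution. Deficits
# are quantified against the predictive median (most likely loss) and the
# 95% bounds (min-max range), then summed over flagged provinces per region.
# With ground truth at hand, the flags are also scored against the injected
# drops.

suppressPackageStartupMessages(library(huntcast))

panel <- read_panel("results/data/panel.csv")
pred <- read.csv("results/predictive_summary.csv", stringsAsFactors = FALSE)
truth <- read.csv("results/data/ground_truth.csv", stringsAsFactors = FALSE)

records <- list()
for (yr in 2020:2021) {
  rec <- flag_anomalies(pred, panel, yr)
  records[[as.character(yr)]] <- rec
  agg <- aggregate_region(rec)
  message(sprintf("season %d: %d provinces flagged as anomalous decreases",
                  yr, sum(rec$flag == "decrease")))
  for (i in which(agg$n_flagged > 0)) {
    with(agg[i, ], message(sprintf(
      "  %s: %0.f fewer licenses than expected (%0.f-%0.f), %d provinces",
      region, deficit_median, deficit_lo, deficit_hi, n_flagged)))
  }
}
all_rec <- do.call(rbind, records)
write.csv(all_rec, "results/anomalies.csv", row.names = FALSE, quote = FALSE)
write.csv(do.call(rbind, lapply(records, aggregate_region)),
          "results/regional_aggregates.csv", row.names = FALSE, quote = FALSE)

m <- merge(all_rec, truth, by = "province")
sens <- mean(m$flag[m$affected] == "decrease")
fpr <- mean(m$flag[!m$affected] == "decrease")
message(sprintf("against ground truth: sensitivity %.0f%%, false positives %.1f%%",
                100 * sens, 100 * fpr))
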