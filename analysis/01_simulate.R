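#!/usr/bin/env Rscript

# Stage 1 — generate the study panel.
#
# The original provincial license registries are not redistributable, so the
# analysis runs on a synthetic panel drawn from the generative model the
# pipeline assumes: 50 provinces in 6 regions, seasons 2011-2021, a ~4%/year
# decline, a shared random-walk year effect, near-Poisson dispersion, and
# post-2019 multiplicative drops in 30% of provinces coupled to a simulated
# excess-mortality covariate. Ground truth is kept so later stages can be
# judged against it.

suppressPackageStartupMessages(library(huntcast))

seed <- 20211
dir.create("results/data", showWarnings = FALSE, recursive = TRUE)

sim <- simulate_panel(sim_config(seed = seed))
write_panel(sim$panel, "results/data/panel.csv")
write_covariates(sim$covariates, "results/data/covariates.csv")
write.csv(summarize_truth(sim$truth), "results/data/ground_truth.csv",
          row.names = FALSE, quote = FALSE)

train <- sim$panel[sim$panel$year <= 2019, ]
message(sprintf("panel: %d provinces, %d regions, years %d-%d, %d rows",
                length(panel_provinces(sim$panel)),
                length(unique(sim$panel$region)),
                min(sim$panel$year), max(sim$panel$year), nrow(sim$panel)))
message(sprintf("training counts: median %d, range %d-%d",
                round(median(train$count)), min(train$count), max(train$count)))
message(sprintf("%d provinces carry an injected post-period drop (mean %.1f%%)",
                sum(summarize_truth(sim$truth)$affected),
                100 * mean(sim$truth$drop[sim$truth$drop > 0])))
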