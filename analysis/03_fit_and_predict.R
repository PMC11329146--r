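#!/usr/bin/env Rscript

# Stage 3 — fit the retained model and project counterfactuals.
#
# The negative-binomial hierarchical trend model (random walk + linear trend
# + province intercepts nested in regions) is fitted to 2011-2019 only.
# For 2020 and 2021 the random walk is extended by forward simulation and a
# full posterior-predictive count distribution is drawn per province-year:
# the counterfactual "world without the epidemic" against which the observed
# seasons are judged.

suppressPackageStartupMessages(library(huntcast))

panel <- read_panel("results/data/panel.csv")
split <- split_spec(2011:2019, 2020:2021)
sam <- sampler_config(chains = 2L, iter = 2000L, warmup = 1500L, seed = 403)

fit <- fit_trend_model(panel, split, model_spec(), prior_spec(), sam)
print(fit)
stopifnot(fit$diagnostics$usable)

pred <- predict_counterfactual(fit, 2020:2021, seed = 404)
write.csv(pred, "results/predictive_summary.csv",
          row.names = FALSE, quote = FALSE)

post <- function(p) c(mean = mean(fit$draws[, p]),
                      quantile(fit$draws[, p], c(0.05, 0.95)))
message(sprintf("posterior yearly trend: %.1f%% (90%% CI %.1f%% to %.1f%%)",
                100 * (exp(post("beta")[1]) - 1),
                100 * (exp(post("beta")[2]) - 1),
                100 * (exp(post("beta")[3]) - 1)))
message(sprintf("posterior dispersion theta: %.0f (90%% CI %.0f-%.0f)",
                post("theta")[1], post("theta")[2], post("theta")[3]))
message(sprintf("median predictive interval halfwidth: %.1f%% of the median",
                100 * median((pred$hi95 - pred$lo95) / 2 / pred$median)))
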