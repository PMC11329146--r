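test_that("intercept-only fit recovers the location of constant counts", {
  p <- license_panel(data.frame(province = "A", region = "R1",
                                year = 2011:2019, count = rep(100L, 9)))
  fit <- fit_trend_model(p, split_spec(2011:2019, 2020),
                         model_spec(FALSE, 0L, "global", label = "intercept-only"),
                         prior_spec(), fast_sampler(seed = 1))
  mu_post <- exp(fit$draws[, "alpha"])
  expect_gt(mean(mu_post), 90); expect_lt(mean(mu_post), 110)
  pred <- predict_counterfactual(fit, 2020, seed = 2)
  expect_gt(pred$median, 95); expect_lt(pred$median, 105)
})

test_that("sampler posterior matches grid-quadrature oracle on the 2-parameter submodel", {
  y <- c(12L, 15L, 9L, 14L, 11L)
  p <- license_panel(data.frame(province = "A", region = "R1",
                                year = 2011:2015, count = y))
  fit <- fit_trend_model(p, split_spec(2011:2015, 2016),
                         model_spec(FALSE, 0L, "global", label = "intercept-only"),
                         prior_spec(), fast_sampler(seed = 11, iter = 4000L,
                                                    warmup = 1000L))
  quad <- quadrature_alpha_marginal(y)
  tv <- tv_samples_vs_grid(fit$draws[, "alpha"], quad)
  expect_lt(tv, 0.05)
})

test_that("fit and predict are deterministic given seeds", {
  sim <- small_sim()
  split <- split_spec(2011:2018, 2019)
  f1 <- fit_trend_model(sim$panel, split, model_spec(), prior_spec(),
                        fast_sampler(seed = 5, iter = 300L, warmup = 300L))
  f2 <- fit_trend_model(sim$panel, split, model_spec(), prior_spec(),
                        fast_sampler(seed = 5, iter = 300L, warmup = 300L))
  expect_identical(f1$draws, f2$draws)
  p1 <- predict_counterfactual(f1, 2019, seed = 9)
  p2 <- predict_counterfactual(f2, 2019, seed = 9)
  expect_identical(p1, p2)
  f3 <- fit_trend_model(sim$panel, split, model_spec(), prior_spec(),
                        fast_sampler(seed = 6, iter = 300L, warmup = 300L))
  expect_false(identical(f1$draws, f3$draws))
})

test_that("predictive medians scale with a common multiplicative shift of the data", {
  sim <- small_sim(seed = 17)
  split <- split_spec(2011:2018, 2019)
  p1 <- sim$panel
  p2 <- p1; p2$count <- as.integer(round(p1$count * 3))
  class(p2) <- class(p1)
  f1 <- fit_trend_model(p1, split, model_spec(), prior_spec(), fast_sampler(seed = 4))
  f2 <- fit_trend_model(p2, split, model_spec(), prior_spec(), fast_sampler(seed = 4))
  m1 <- predict_counterfactual(f1, 2019, seed = 8)$median
  m2 <- predict_counterfactual(f2, 2019, seed = 8)$median
  expect_equal(m2 / m1, rep(3, length(m1)), tolerance = 0.05)
})

test_that("degenerate point-mass draws give the NB quantile limit", {
  # all posterior mass at one parameter point, tiny sigma_gamma, huge theta:
  # predictive median ~ exp(linear predictor), interval ~ NB quantile width
  p <- license_panel(data.frame(province = "A", region = "R1",
                                year = 2011:2019, count = rep(5000L, 9)))
  fit <- fit_trend_model(p, split_spec(2011:2019, 2020),
                         model_spec(FALSE, 0L, "global", label = "intercept-only"),
                         prior_spec(), fast_sampler(seed = 2, iter = 2000L))
  eta <- log(5000)
  fit$draws[, "alpha"] <- eta
  fit$draws[, "theta"] <- 1e8
  fit$draws[, "sigma_gamma"] <- 0
  pred <- predict_counterfactual(fit, 2020, seed = 3)
  expect_equal(pred$median, round(exp(eta)), tolerance = 0.002)
  nb_lo <- qnbinom(0.025, size = 1e8, mu = exp(eta))
  nb_hi <- qnbinom(0.975, size = 1e8, mu = exp(eta))
  expect_equal(pred$lo95, nb_lo, tolerance = 0.002)
  expect_equal(pred$hi95, nb_hi, tolerance = 0.002)
})

test_that("prediction refuses evaluation years inside the training window", {
  sim <- small_sim()
  fit <- fit_trend_model(sim$panel, split_spec(2011:2018, 2019), model_spec(),
                         prior_spec(), fast_sampler(iter = 200L, warmup = 200L))
  expect_error(predict_counterfactual(fit, 2018, seed = 1), "strictly after")
})

test_that("fitting requires at least 3 training years per province", {
  p <- license_panel(data.frame(province = c("A", "A", "B"), region = "R1",
                                year = c(2011L, 2012L, 2011L),
                                count = c(10L, 11L, 12L)))
  expect_error(
    fit_trend_model(p, split_spec(2011:2012, 2013), model_spec(), prior_spec(),
                    fast_sampler()),
    "at least 3 training years.*B")
})

test_that("pointwise log density matches direct NB pmf evaluation", {
  sim <- small_sim()
  split <- split_spec(2011:2018, 2019)
  fit <- fit_trend_model(sim$panel, split, model_spec(), prior_spec(),
                         fast_sampler(iter = 50L, warmup = 200L))
  # single draw: lpd is exactly the per-draw NB log-pmf
  d1 <- fit$draws[1L, , drop = FALSE]
  fit1 <- fit; fit1$draws <- d1
  lpd1 <- log_pointwise_density(fit1, sim$panel)
  cell1 <- sim$panel[sim$panel$province == "P01" & sim$panel$year == 2011, ]
  eta <- d1[, "alpha"] + d1[, "u[R01]"] + d1[, "v[P01]"] + d1[, "gamma[2011]"]
  expect_equal(unname(lpd1["P01 2011"]),
               dnbinom(cell1$count, size = d1[, "theta"], mu = exp(eta),
                       log = TRUE),
               tolerance = 1e-12)
  # two identical draws: log-mean-exp of equal values is the one-draw value
  fit2 <- fit; fit2$draws <- rbind(d1, d1)
  expect_equal(log_pointwise_density(fit2, sim$panel), lpd1, tolerance = 1e-12)
  # random small case: matches high-precision direct summation over draws
  fitN <- fit
  lpdN <- log_pointwise_density(fitN, sim$panel)
  cell <- "P04 2015"
  row <- sim$panel[sim$panel$province == "P04" & sim$panel$year == 2015, ]
  per_draw <- apply(fit$draws, 1L, function(d) {
    eta <- d["alpha"] + d["u[R02]"] + d["v[P04]"] + d["beta"] * 4 + d["gamma[2015]"]
    dnbinom(row$count, size = d["theta"], mu = exp(eta), log = TRUE)
  })
  m <- max(per_draw)
  expect_equal(unname(lpdN[cell]), m + log(sum(exp(per_draw - m)) / length(per_draw)),
               tolerance = 1e-10)
})

test_that("missing cells requested for scoring are excluded and reported", {
  sim <- small_sim()
  fit <- fit_trend_model(sim$panel, split_spec(2011:2018, 2019), model_spec(),
                         prior_spec(), fast_sampler(iter = 100L, warmup = 200L))
  cells <- data.frame(province = c("P01", "P01"), year = c(2011L, 1999L))
  lpd <- log_pointwise_density(fit, sim$panel, cells)
  expect_length(lpd, 1L)
  expect_equal(attr(lpd, "missing_cells"), "P01 1999")
})

test_that("predictive median is Monte-Carlo stable in the number of draws", {
  sim <- small_sim(seed = 23, theta = 1000)
  fit <- fit_trend_model(sim$panel, split_spec(2011:2018, 2019), model_spec(),
                         prior_spec(), fast_sampler(seed = 31, iter = 5000L,
                                                    warmup = 1000L))
  # evenly thinned 1,000-draw subset of the 10,000 available draws
  fit_small <- fit
  fit_small$draws <- fit$draws[seq(1L, nrow(fit$draws), by = 10L), , drop = FALSE]
  m_small <- predict_counterfactual(fit_small, 2019, seed = 77)$median
  m_full <- predict_counterfactual(fit, 2019, seed = 78)$median  # 10,000 draws
  expect_true(all(abs(m_full - m_small) / m_full < 0.01))
})

test_that("non-convergence is flagged, not silently accepted", {
  sim <- small_sim()
  # absurdly short chains on the full hierarchical model cannot converge
  fit <- fit_trend_model(sim$panel, split_spec(2011:2018, 2019), model_spec(),
                         prior_spec(),
                         sampler_config(chains = 2L, iter = 20L, warmup = 5L,
                                        seed = 1))
  expect_false(fit$diagnostics$usable)
  expect_gt(fit$diagnostics$max_rhat, 1.05)
})
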