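# Shared fixtures and independent oracles used across the suite.

# minimal well-formed panel
tiny_panel <- function() {
  license_panel(data.frame(
    province = "A", region = "R1", year = 2011:2013, count = c(10L, 9L, 8L),
    stringsAsFactors = FALSE
  ))
}

# small simulated panel for fast model fits: 5 provinces, 2 regions, 8 years
small_sim <- function(seed = 7, theta = 50, ...) {
  simulate_panel(sim_config(seed = seed, n_regions = 2L,
                            provinces_per_region = c(3L, 2L),
                            years = 2011:2019, training_cutoff = 2018L,
                            theta = theta, affected_fraction = 0, ...))
}

fast_sampler <- function(seed = 3, iter = 800L, warmup = 800L, chains = 2L) {
  sampler_config(chains = chains, iter = iter, warmup = warmup, seed = seed)
}

# Brute-force tie-aware Spearman oracle: midranks assigned by direct
# counting (#smaller + (#equal + 1)/2), Pearson by explicit summation.
bf_spearman <- function(x, y) {
  midrank <- function(z) {
    vapply(z, function(zi) sum(z < zi) + (sum(z == zi) + 1) / 2, numeric(1))
  }
  a <- midrank(x); b <- midrank(y)
  n <- length(a)
  num <- n * sum(a * b) - sum(a) * sum(b)
  den <- sqrt((n * sum(a^2) - sum(a)^2) * (n * sum(b^2) - sum(b)^2))
  num / den
}

# Grid-quadrature posterior for the 2-parameter intercept-only NB model
# (global intercept alpha, dispersion theta) under the package's priors.
# Returns the alpha marginal on a fine grid; independent of the sampler.
quadrature_alpha_marginal <- function(y, alpha_sd = 1.5, theta_rate = 0.1,
                                      half_width = 1.2, n_grid = 400L) {
  am <- log(mean(y) + 0.5)
  agrid <- seq(am - half_width, am + half_width, length.out = n_grid)
  ltgrid <- seq(log(0.05), log(2000), length.out = n_grid)
  lp <- matrix(NA_real_, n_grid, n_grid)
  for (j in seq_along(ltgrid)) {
    th <- exp(ltgrid[j])
    ll <- vapply(agrid, function(al)
      sum(stats::dnbinom(y, size = th, mu = exp(al), log = TRUE)), numeric(1))
    # Exponential(theta_rate) prior on 1/theta, as a density in log theta
    lp[, j] <- ll + stats::dnorm(agrid, am, alpha_sd, log = TRUE) -
      theta_rate / th - ltgrid[j]
  }
  w <- exp(lp - max(lp))
  marg <- rowSums(w)
  list(grid = agrid, prob = marg / sum(marg), center = am,
       half_width = half_width)
}

# total variation distance between MCMC samples and a grid marginal,
# both binned on a common partition
tv_samples_vs_grid <- function(samples, quad, n_bins = 40L) {
  breaks <- seq(quad$center - quad$half_width, quad$center + quad$half_width,
                length.out = n_bins + 1L)
  pg <- tapply(quad$prob, cut(quad$grid, breaks), sum)
  pg[is.na(pg)] <- 0
  samples <- pmin(pmax(samples, breaks[1]), breaks[length(breaks)])
  pm <- table(cut(samples, breaks)) / length(samples)
  0.5 * sum(abs(pg - as.numeric(pm)))
}
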