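#' Configuration for the synthetic panel generator
#'
#' Defines the generative model the analysis assumes: province-year counts
#' drawn from a negative binomial with mean
#' `log mu[p,t] = alpha + u[region(p)] + v[p] + beta * (t - t0) + gamma[t]`
#' where `u`, `v` are region and province intercept deviations, `beta` a
#' shared log-linear year trend, and `gamma` a shared first-order random walk
#' anchored at the first year (`gamma[t0] = 0`). For years after
#' `training_cutoff`, a fraction of provinces receives a multiplicative drop
#' `d[p]`, i.e. `log mu` is offset by `log(1 - d[p])`, with
#' `d[p] = drop_intercept + drop_slope * e[p]/100 + Normal(0, drop_sd)`
#' clipped to `[0, 0.35]`, coupling the drop to a simulated excess-mortality
#' covariate `e[p] ~ Uniform(mortality_lo, mortality_hi)` (percent).
#'
#' Defaults emulate the Northern-Italy license registries the model was built
#' for: 50 provinces in 6 regions, seasons 2011-2021 with a 2019 training
#' cutoff, counts roughly 1,100-9,600, a long-term decline of about 4%/year,
#' near-Poisson dispersion (the registries are administrative totals, so
#' year-to-year noise is small relative to the counts), and post-period drops
#' of 0-30% rank-correlated with the covariate.
#'
#' @param n_regions number of regions.
#' @param provinces_per_region integer vector (recycled) of provinces in each
#'   region; defaults sum to 50.
#' @param years calendar years labelling each season's opening.
#' @param training_cutoff last pre-period year; later years are post-period.
#' @param alpha global intercept on the log scale.
#' @param sigma_u,sigma_v region and province intercept sds (log scale).
#' @param beta log-linear trend per year; default `log(0.96)` (~4% decline).
#' @param sigma_gamma random-walk innovation sd (log scale).
#' @param theta negative-binomial dispersion, `Var = mu + mu^2/theta`.
#' @param affected_fraction fraction of provinces given a post-period drop.
#' @param drop_intercept,drop_slope,drop_sd drop-size line coefficients.
#' @param mortality_lo,mortality_hi covariate range in percent.
#' @param seed mandatory integer seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_regions = 6L,
                       provinces_per_region = c(9L, 9L, 8L, 8L, 8L, 8L),
                       years = 2011:2021,
                       training_cutoff = 2019L,
                       alpha = log(3200),
                       sigma_u = 0.25,
                       sigma_v = 0.45,
                       beta = log(0.96),
                       sigma_gamma = 0.02,
                       theta = 1000,
                       affected_fraction = 0.3,
                       drop_intercept = 0.05,
                       drop_slope = 0.25,
                       drop_sd = 0.08,
                       mortality_lo = 0,
                       mortality_hi = 60,
                       seed) {
  if (missing(seed)) stop("sim_config: seed is mandatory", call. = FALSE)
  cfg <- list(
    n_regions = as.integer(n_regions),
    provinces_per_region = rep_len(as.integer(provinces_per_region), n_regions),
    years = sort(as.integer(years)),
    training_cutoff = as.integer(training_cutoff),
    alpha = alpha, sigma_u = sigma_u, sigma_v = sigma_v,
    beta = beta, sigma_gamma = sigma_gamma, theta = theta,
    affected_fraction = affected_fraction,
    drop_intercept = drop_intercept, drop_slope = drop_slope, drop_sd = drop_sd,
    mortality_lo = mortality_lo, mortality_hi = mortality_hi,
    seed = as.integer(seed)
  )
  with(cfg, {
    if (sigma_u < 0 || sigma_v < 0 || sigma_gamma < 0)
      stop("sim_config: sds must be >= 0", call. = FALSE)
    if (theta <= 0) stop("sim_config: theta must be > 0", call. = FALSE)
    if (affected_fraction < 0 || affected_fraction > 1)
      stop("sim_config: affected_fraction must be in [0, 1]", call. = FALSE)
    if (drop_sd < 0) stop("sim_config: drop_sd must be >= 0", call. = FALSE)
    if (mortality_hi < mortality_lo)
      stop("sim_config: mortality_hi < mortality_lo", call. = FALSE)
  })
  structure(cfg, class = "sim_config")
}

#' Simulate a license panel with known ground truth
#'
#' Draws a full panel from the generative model described in [sim_config()],
#' returning the panel, a per-province covariate table for the post-period
#' seasons, and the ground truth (all latent effects, injected drops) needed
#' for recovery tests. Identical seeds give identical output.
#'
#' @param config a `sim_config`.
#' @return list with elements `panel` (a [license_panel()]), `covariates`
#'   (province, year, excess_mortality_pct for post-period years) and `truth`.
#' @export
simulate_panel <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  nR <- config$n_regions
  nP <- sum(config$provinces_per_region)
  regions <- sprintf("R%02d", seq_len(nR))
  region_of <- rep(regions, config$provinces_per_region)
  provinces <- sprintf("P%02d", seq_len(nP))
  years <- config$years
  nT <- length(years)
  t0 <- years[1L]

  u <- if (config$sigma_u > 0) stats::rnorm(nR, 0, config$sigma_u) else numeric(nR)
  v <- if (config$sigma_v > 0) stats::rnorm(nP, 0, config$sigma_v) else numeric(nP)
  gamma <- c(0, cumsum(stats::rnorm(nT - 1L, 0, config$sigma_gamma)))
  names(gamma) <- as.character(years)

  e <- stats::runif(nP, config$mortality_lo, config$mortality_hi)
  n_affected <- round(config$affected_fraction * nP)
  affected <- sort(sample.int(nP, n_affected))
  d <- numeric(nP)
  if (n_affected > 0L) {
    raw <- config$drop_intercept + config$drop_slope * e[affected] / 100 +
      stats::rnorm(n_affected, 0, config$drop_sd)
    d[affected] <- pmin(pmax(raw, 0), 0.35)
  }

  grid <- expand.grid(p = seq_len(nP), t = seq_len(nT))
  post <- years[grid$t] > config$training_cutoff
  log_mu <- config$alpha + u[match(region_of, regions)][grid$p] + v[grid$p] +
    config$beta * (years[grid$t] - t0) + gamma[grid$t] +
    ifelse(post & d[grid$p] > 0, log1p(-d[grid$p]), 0)
  counts <- stats::rnbinom(nrow(grid), size = config$theta, mu = exp(log_mu))

  panel <- license_panel(data.frame(
    province = provinces[grid$p],
    region = region_of[grid$p],
    year = years[grid$t],
    count = counts,
    stringsAsFactors = FALSE
  ))

  post_years <- years[years > config$training_cutoff]
  covariates <- expand.grid(province = provinces, year = post_years,
                            stringsAsFactors = FALSE)
  covariates$excess_mortality_pct <- round(e[match(covariates$province, provinces)], 1)
  covariates <- covariates[order(covariates$province, covariates$year), ]
  rownames(covariates) <- NULL

  drops <- expand.grid(province = provinces, year = post_years,
                       stringsAsFactors = FALSE)
  drops$drop <- d[match(drops$province, provinces)]

  truth <- list(
    alpha = config$alpha, beta = config$beta, theta = config$theta,
    sigma_gamma = config$sigma_gamma,
    u = stats::setNames(u, regions), v = stats::setNames(v, provinces),
    gamma = gamma,
    region_of = stats::setNames(region_of, provinces),
    covariate = stats::setNames(e, provinces),
    drop = stats::setNames(d, provinces),
    drops_by_year = drops,
    affected = provinces[affected],
    config = config
  )
  list(panel = panel, covariates = covariates, truth = truth)
}

#' Flatten simulation ground truth to a per-province table
#'
#' @param truth the `truth` element returned by [simulate_panel()].
#' @return data.frame with one row per province: region, injected drop,
#'   covariate value, and whether the province was affected.
#' @export
summarize_truth <- function(truth) {
  provinces <- names(truth$drop)
  data.frame(
    province = provinces,
    region = unname(truth$region_of[provinces]),
    drop = unname(truth$drop[provinces]),
    excess_mortality_pct = unname(truth$covariate[provinces]),
    affected = provinces %in% truth$affected,
    stringsAsFactors = FALSE
  )
}
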