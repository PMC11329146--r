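#' Candidate model structures
#'
#' A model spec names one spatiotemporal structure for the license-count
#' trend model: whether a shared log-linear year trend is included, whether a
#' shared first-order random-walk year effect is included, and the random
#' intercept structure (region-only, province-only, province nested in
#' region, or a single global intercept). The default — random walk plus
#' linear trend with province intercepts nested in regions — is the structure
#' needed to produce province-specific counterfactuals.
#'
#' @param include_linear_trend include the shared log-linear year trend?
#' @param rw_order 0 (none) or 1 (first-order random walk year effect).
#' @param intercept_structure random intercept layout.
#' @param label candidate label; auto-generated when `NULL`.
#' @return A `model_spec`.
#' @export
model_spec <- function(include_linear_trend = TRUE,
                       rw_order = 1L,
                       intercept_structure = c("province-nested-in-region",
                                               "region-only", "province-only",
                                               "global"),
                       label = NULL) {
  intercept_structure <- match.arg(intercept_structure)
  rw_order <- as.integer(rw_order)
  if (!rw_order %in% c(0L, 1L)) stop("model_spec: rw_order must be 0 or 1", call. = FALSE)
  if (is.null(label)) {
    label <- paste0(
      if (rw_order == 1L) "rw" else NULL,
      if (include_linear_trend) "linear" else NULL,
      if (!rw_order && !include_linear_trend) "intercept-only" else NULL,
      collapse = ""
    )
    label <- paste(c(if (rw_order == 1L) "rw",
                     if (include_linear_trend) "linear",
                     if (rw_order == 0L && !include_linear_trend) "intercept-only",
                     intercept_structure), collapse = "+")
  }
  structure(list(include_linear_trend = include_linear_trend,
                 rw_order = rw_order,
                 intercept_structure = intercept_structure,
                 label = label),
            class = "model_spec")
}

#' Default candidate set for model selection
#'
#' Spans the plausible structures for an annual count panel with a long-term
#' decline: linear trend only, random walk only, both combined, and the
#' combined structure under region-only versus nested intercepts.
#'
#' @return list of [model_spec()] objects.
#' @export
default_candidates <- function() {
  list(
    model_spec(TRUE, 0L, "province-nested-in-region", label = "linear-only"),
    model_spec(FALSE, 1L, "province-nested-in-region", label = "rw-only"),
    model_spec(TRUE, 1L, "global", label = "rw+linear"),
    model_spec(TRUE, 1L, "region-only", label = "rw+linear+region"),
    model_spec(TRUE, 1L, "province-nested-in-region", label = "rw+linear+nested")
  )
}

#' Prior specification
#'
#' Weakly informative defaults: the global intercept is centred on the log
#' grand mean count (computed from the training data when `alpha_mean` is
#' `NA`) with sd 1.5; the yearly log-trend gets a Normal(0, 0.2) prior (a
#' +-20%/year change is already extreme for license renewals); half-Normal
#' priors on the random-effect sds; and an Exponential(0.1) prior on the
#' reciprocal dispersion 1/theta, which is essentially flat near the Poisson
#' limit (large theta) while remaining proper.
#'
#' @param alpha_mean prior mean for the global intercept (log scale); `NA`
#'   means "use the log grand mean of the training counts".
#' @param alpha_sd,beta_sd prior sds for intercept and linear trend.
#' @param sigma_u_scale,sigma_v_scale,sigma_gamma_scale half-Normal scales
#'   for the region, province and random-walk innovation sds.
#' @param theta_rate rate of the Exponential prior on 1/theta.
#' @return A `prior_spec`.
#' @export
prior_spec <- function(alpha_mean = NA_real_, alpha_sd = 1.5,
                       beta_sd = 0.2,
                       sigma_u_scale = 1, sigma_v_scale = 1,
                       sigma_gamma_scale = 0.5,
                       theta_rate = 0.1) {
  stopifnot(alpha_sd > 0, beta_sd > 0, sigma_u_scale > 0, sigma_v_scale > 0,
            sigma_gamma_scale > 0, theta_rate > 0)
  structure(list(alpha_mean = alpha_mean, alpha_sd = alpha_sd,
                 beta_sd = beta_sd,
                 sigma_u_scale = sigma_u_scale, sigma_v_scale = sigma_v_scale,
                 sigma_gamma_scale = sigma_gamma_scale,
                 theta_rate = theta_rate),
            class = "prior_spec")
}

#' Sampler configuration
#'
#' @param chains number of MCMC chains (>= 2 recommended for diagnostics).
#' @param iter post-warmup draws per chain.
#' @param warmup adaptation iterations per chain (discarded).
#' @param thin keep every `thin`-th post-warmup draw.
#' @param seed integer seed; mandatory for reproducibility.
#' @return A `sampler_config`.
#' @export
sampler_config <- function(chains = 2L, iter = 1000L, warmup = 1000L,
                           thin = 1L, seed) {
  if (missing(seed)) stop("sampler_config: seed is mandatory", call. = FALSE)
  stopifnot(chains >= 1, iter >= 1, warmup >= 0, thin >= 1)
  structure(list(chains = as.integer(chains), iter = as.integer(iter),
                 warmup = as.integer(warmup), thin = as.integer(thin),
                 seed = as.integer(seed)),
            class = "sampler_config")
}

#' Fit the Bayesian negative-binomial hierarchical trend model
#'
#' Samples the posterior of
#' `log mu[p,t] = alpha + u[r(p)] + v[p] + beta*(t - t0) + gamma[t]`,
#' `y[p,t] ~ NegBin(mu[p,t], theta)`, on the training years of the split,
#' using an adaptive Metropolis-within-Gibbs sampler. The random-walk states
#' are anchored at `gamma[t0] = 0`, the time covariate is centred at the
#' first training year, and reported draws carry the sum-to-zero
#' identification of `u` and `v`.
#'
#' @param panel a [license_panel()].
#' @param split a [split_spec()]; only training years are used.
#' @param spec a [model_spec()].
#' @param priors a [prior_spec()].
#' @param sampler a [sampler_config()].
#' @return An object of class `hc_fit`: posterior draw matrix (rows = draws,
#'   labelled columns), per-chain layout, convergence diagnostics (split-Rhat
#'   and effective sample size per parameter, `usable` flag set to `FALSE` if
#'   any Rhat exceeds 1.05), and the index structures needed for prediction.
#' @export
fit_trend_model <- function(panel, split, spec = model_spec(),
                            priors = prior_spec(), sampler) {
  stopifnot(inherits(panel, "license_panel"), inherits(split, "split_spec"),
            inherits(spec, "model_spec"), inherits(priors, "prior_spec"),
            inherits(sampler, "sampler_config"))
  train <- panel[panel$year %in% split$training_years, , drop = FALSE]
  if (nrow(train) == 0L) stop("fit_trend_model: no training data", call. = FALSE)
  n_per_prov <- table(train$province)
  if (any(n_per_prov < 3L))
    stop("fit_trend_model: at least 3 training years required per province; ",
         "offending province(s): ",
         paste(names(n_per_prov)[n_per_prov < 3L], collapse = ", "),
         call. = FALSE)

  provinces <- sort(unique(train$province))
  region_of <- panel_region_of(train)[provinces]
  regions <- sort(unique(region_of))
  years <- sort(unique(train$year))
  t0 <- years[1L]
  nP <- length(provinces); nR <- length(regions); nT <- length(years)

  use_u <- spec$intercept_structure %in% c("region-only", "province-nested-in-region") && nR > 1L
  use_v <- spec$intercept_structure %in% c("province-only", "province-nested-in-region") && nP > 1L
  use_rw <- spec$rw_order == 1L
  use_linear <- isTRUE(spec$include_linear_trend)

  pr <- unclass(priors)
  if (is.na(pr$alpha_mean)) pr$alpha_mean <- log(mean(train$count) + 0.5)

  y <- as.integer(train$count)
  prov_i <- match(train$province, provinces) - 1L
  reg_i <- match(region_of[train$province], regions) - 1L
  t_i <- match(train$year, years) - 1L

  par_names <- c("alpha", "beta",
                 paste0("u[", regions, "]"),
                 paste0("v[", provinces, "]"),
                 paste0("gamma[", years, "]"),
                 "sigma_u", "sigma_v", "sigma_gamma", "theta")

  chain_draws <- vector("list", sampler$chains)
  for (ch in seq_len(sampler$chains)) {
    set.seed(sampler$seed + 1000L * (ch - 1L))
    inits <- list(alpha = log(mean(y) + 0.5) + stats::rnorm(1, 0, 0.1),
                  beta = stats::rnorm(1, 0, 0.02),
                  sigma_u = stats::runif(1, 0.1, 0.4),
                  sigma_v = stats::runif(1, 0.1, 0.4),
                  sigma_gamma = stats::runif(1, 0.02, 0.1),
                  theta = exp(stats::runif(1, log(20), log(500))))
    out <- nb_mwg_sampler(y, prov_i, reg_i, t_i, nP, nR, nT,
                          use_linear, use_rw, use_u, use_v,
                          pr, sampler$iter, sampler$warmup, sampler$thin,
                          inits)
    colnames(out$draws) <- par_names
    chain_draws[[ch]] <- out$draws
  }

  draws <- do.call(rbind, chain_draws)
  active <- active_parameters(par_names, use_linear, use_rw, use_u, use_v,
                              regions, provinces, years)
  diag <- fit_diagnostics(chain_draws, active)

  structure(list(draws = draws, chain_draws = chain_draws,
                 diagnostics = diag,
                 spec = spec, priors = pr, sampler = sampler, split = split,
                 provinces = provinces, regions = regions,
                 region_of = region_of, years = years, t0 = t0,
                 use = list(linear = use_linear, rw = use_rw,
                            u = use_u, v = use_v),
                 train = train),
            class = "hc_fit")
}

active_parameters <- function(par_names, use_linear, use_rw, use_u, use_v,
                              regions, provinces, years) {
  keep <- c("alpha", "theta")
  if (use_linear) keep <- c(keep, "beta")
  if (use_u) keep <- c(keep, paste0("u[", regions, "]"), "sigma_u")
  if (use_v) keep <- c(keep, paste0("v[", provinces, "]"), "sigma_v")
  if (use_rw) keep <- c(keep, paste0("gamma[", years[-1L], "]"), "sigma_gamma")
  intersect(par_names, keep)
}

# split-Rhat and a crude effective sample size over all chains
fit_diagnostics <- function(chain_draws, active) {
  rhat <- vapply(active, function(p) {
    split_rhat(lapply(chain_draws, function(m) m[, p]))
  }, numeric(1))
  ess <- vapply(active, function(p) {
    sum(vapply(chain_draws, function(m) ess_acf(m[, p]), numeric(1)))
  }, numeric(1))
  list(rhat = rhat, ess = ess,
       max_rhat = max(rhat, na.rm = TRUE),
       usable = all(is.na(rhat) | rhat <= 1.05))
}

split_rhat <- function(chains) {
  halves <- unlist(lapply(chains, function(x) {
    n <- length(x) %/% 2L
    list(x[seq_len(n)], x[n + seq_len(n)])
  }), recursive = FALSE)
  m <- length(halves); n <- length(halves[[1L]])
  if (n < 2L) return(NA_real_)
  means <- vapply(halves, mean, numeric(1))
  vars <- vapply(halves, stats::var, numeric(1))
  W <- mean(vars)
  B <- n * stats::var(means)
  if (!is.finite(W) || W <= .Machine$double.eps) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

ess_acf <- function(x) {
  n <- length(x)
  if (stats::var(x) <= .Machine$double.eps) return(n)
  lag_max <- min(n - 1L, 200L)
  rho <- stats::acf(x, lag.max = lag_max, plot = FALSE)$acf[-1L]
  # Geyer-style truncation: stop at first negative pair sum
  s <- 0; k <- 1L
  while (k + 1L <= length(rho)) {
    pair <- rho[k] + rho[k + 1L]
    if (pair < 0) break
    s <- s + pair
    k <- k + 2L
  }
  max(1, n / (1 + 2 * s))
}

#' @export
print.hc_fit <- function(x, ...) {
  cat("<hc_fit> ", x$spec$label, "\n",
      "  provinces: ", length(x$provinces),
      "  regions: ", length(x$regions),
      "  training years: ", min(x$years), "-", max(x$years), "\n",
      "  draws: ", nrow(x$draws), " (", x$sampler$chains, " chains)\n",
      "  max split-Rhat: ", round(x$diagnostics$max_rhat, 3),
      if (!x$diagnostics$usable) "  [NOT CONVERGED]" else "", "\n", sep = "")
  invisible(x)
}
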