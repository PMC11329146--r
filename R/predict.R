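#' Posterior-predictive counterfactual for post-period years
#'
#' For each posterior draw, the random walk is extended forward from the last
#' training year by `gamma[T+k] = gamma[T+k-1] + Normal(0, sigma_gamma)`, the
#' linear trend is extrapolated, and one count is drawn from
#' `NegBin(exp(linear predictor), theta)`. The per-cell predictive median and
#' central 95% interval are computed across draws; these are the
#' counterfactual "what would have happened" distributions against which
#' observed post-period counts are compared.
#'
#' @param fit an `hc_fit` from [fit_trend_model()].
#' @param evaluation_years years to predict; all must lie strictly after the
#'   last training year.
#' @param seed integer seed for the forward simulation.
#' @param keep_draws retain the predictive draw matrix (needed e.g. for
#'   Monte-Carlo stability checks)?
#' @return A `predictive_summary` data.frame: `province`, `region`, `year`,
#'   `median`, `lo95`, `hi95`; with the draw array as attribute `draws` when
#'   `keep_draws = TRUE`.
#' @export
predict_counterfactual <- function(fit, evaluation_years, seed,
                                   keep_draws = FALSE) {
  stopifnot(inherits(fit, "hc_fit"))
  if (missing(seed)) stop("predict_counterfactual: seed is mandatory", call. = FALSE)
  evaluation_years <- sort(as.integer(evaluation_years))
  last_train <- max(fit$years)
  if (any(evaluation_years <= last_train))
    stop("predict_counterfactual: evaluation years must be strictly after ",
         last_train, call. = FALSE)

  set.seed(seed)
  d <- fit$draws
  S <- nrow(d)
  nP <- length(fit$provinces)
  horizon <- max(evaluation_years) - last_train

  alpha <- d[, "alpha"]
  beta <- if (fit$use$linear) d[, "beta"] else numeric(S)
  theta <- d[, "theta"]
  u <- if (fit$use$u) d[, paste0("u[", fit$region_of[fit$provinces], "]"), drop = FALSE]
       else matrix(0, S, nP)
  v <- if (fit$use$v) d[, paste0("v[", fit$provinces, "]"), drop = FALSE]
       else matrix(0, S, nP)

  # forward-simulate the random walk: S x horizon matrix of gamma states
  if (fit$use$rw) {
    g_last <- d[, paste0("gamma[", last_train, "]")]
    sg <- d[, "sigma_gamma"]
    innov <- matrix(stats::rnorm(S * horizon), S, horizon) * sg
    g_fwd <- g_last + t(apply(innov, 1L, cumsum))
    if (horizon == 1L) g_fwd <- matrix(g_last + innov[, 1L], S, 1L)
  } else {
    g_fwd <- matrix(0, S, horizon)
  }

  out <- vector("list", length(evaluation_years))
  draw_arrays <- if (keep_draws) vector("list", length(evaluation_years))
  for (k in seq_along(evaluation_years)) {
    yr <- evaluation_years[k]
    x <- yr - fit$t0
    eta <- alpha + beta * x + g_fwd[, yr - last_train] + u + v  # S x nP
    ystar <- matrix(stats::rnbinom(S * nP, size = theta, mu = exp(eta)), S, nP)
    q <- apply(ystar, 2L, stats::quantile, probs = c(0.025, 0.5, 0.975),
               names = FALSE)
    out[[k]] <- data.frame(
      province = fit$provinces,
      region = unname(fit$region_of[fit$provinces]),
      year = yr,
      median = q[2L, ], lo95 = q[1L, ], hi95 = q[3L, ],
      stringsAsFactors = FALSE
    )
    if (keep_draws) {
      colnames(ystar) <- fit$provinces
      draw_arrays[[k]] <- ystar
    }
  }
  res <- do.call(rbind, out)
  res <- res[order(res$region, res$province, res$year), ]
  rownames(res) <- NULL
  class(res) <- c("predictive_summary", "data.frame")
  if (keep_draws) attr(res, "draws") <- stats::setNames(draw_arrays,
                                                        evaluation_years)
  res
}

# per-draw NB log-likelihood matrix (S x n_cells) for given panel cells
loglik_matrix <- function(fit, panel, cells = NULL) {
  train_years <- fit$years
  obs <- panel[panel$year %in% train_years & panel$province %in% fit$provinces, ,
               drop = FALSE]
  if (!is.null(cells)) {
    key <- paste(obs$province, obs$year)
    want <- paste(cells$province, cells$year)
    missing_cells <- setdiff(want, key)
    obs <- obs[match(intersect(want, key), key), , drop = FALSE]
    attr(obs, "missing_cells") <- missing_cells
  }
  d <- fit$draws
  S <- nrow(d)
  eta <- matrix(d[, "alpha"], S, nrow(obs))
  if (fit$use$linear) eta <- eta + outer(d[, "beta"], obs$year - fit$t0)
  if (fit$use$u) eta <- eta + d[, paste0("u[", fit$region_of[obs$province], "]"), drop = FALSE]
  if (fit$use$v) eta <- eta + d[, paste0("v[", obs$province, "]"), drop = FALSE]
  if (fit$use$rw) eta <- eta + d[, paste0("gamma[", obs$year, "]"), drop = FALSE]
  ll <- matrix(stats::dnbinom(rep(obs$count, each = S), size = d[, "theta"],
                              mu = exp(eta), log = TRUE), S, nrow(obs))
  colnames(ll) <- paste(obs$province, obs$year)
  attr(ll, "cells") <- obs[, c("province", "year", "count")]
  attr(ll, "missing_cells") <- attr(obs, "missing_cells")
  ll
}

log_mean_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(mean(exp(x - m)))
}

#' Pointwise log predictive density
#'
#' Per-observation log predictive density averaged over posterior draws
#' (the log-mean-exp of the per-draw negative-binomial log-pmf); the
#' building block of leave-one-out model comparison.
#'
#' @param fit an `hc_fit`.
#' @param panel a [license_panel()] holding the observations to score.
#' @param cells optional data.frame (`province`, `year`) restricting which
#'   training cells are scored; cells absent from the panel are excluded and
#'   reported in attribute `missing_cells`.
#' @return Named numeric vector of per-cell log predictive densities.
#' @export
log_pointwise_density <- function(fit, panel, cells = NULL) {
  ll <- loglik_matrix(fit, panel, cells)
  lpd <- apply(ll, 2L, log_mean_exp)
  attr(lpd, "missing_cells") <- attr(ll, "missing_cells")
  lpd
}
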