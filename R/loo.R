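# Generalized Pareto fit to upper-tail importance ratios, by the
# Zhang & Stephens (2009) profile-posterior method. Returns shape k and
# scale sigma for exceedances x (already shifted to start at ~0).
gpd_fit <- function(x) {
  x <- sort(x)
  n <- length(x)
  m <- 30L + floor(sqrt(n))
  prior_b <- x[max(1L, floor(n / 4 + 0.5))]
  j <- seq_len(m)
  b <- 1 / x[n] + (1 - sqrt(m / (j - 0.5))) / (3 * prior_b)
  profile_lik <- vapply(b, function(bj) {
    k <- -mean(log1p(-bj * x))
    n * (log(bj / k) + k - 1)
  }, numeric(1))
  w <- exp(profile_lik - max(profile_lik))
  w <- w / sum(w)
  b_hat <- sum(b * w)
  k_hat <- -mean(log1p(-b_hat * x))
  sigma_hat <- k_hat / b_hat
  # small-sample bias correction on k (regularizes noisy tails)
  k_hat <- (n * k_hat + 5) / (n + 10)
  list(k = k_hat, sigma = sigma_hat)
}

# Pareto-smoothed importance weights for one observation.
# lw: raw log weights (log 1/p(y_i | theta_s)); returns smoothed log weights
# (unnormalized) and the tail shape diagnostic k.
psis_smooth <- function(lw) {
  S <- length(lw)
  lw <- lw - max(lw)
  M <- ceiling(min(0.2 * S, 3 * sqrt(S)))
  if (M < 5L) return(list(lw = lw, k = NA_real_))
  ord <- order(lw)
  tail_ids <- ord[(S - M + 1L):S]
  cutoff <- lw[ord[S - M]]
  exceed <- exp(lw[tail_ids]) - exp(cutoff)
  if (max(exceed) <= 0) return(list(lw = lw, k = 0))
  fit <- gpd_fit(exceed)
  k <- fit$k
  if (is.finite(k)) {
    # replace tail by expected order statistics of the fitted GPD
    p <- (seq_len(M) - 0.5) / M
    qgpd <- if (abs(k) < 1e-12) -fit$sigma * log1p(-p)
            else fit$sigma * ((1 - p)^(-k) - 1) / k
    smoothed <- log(exp(cutoff) + qgpd)
    smoothed <- pmin(smoothed, 0)  # truncate at max raw weight (lw max = 0)
    lw[tail_ids[order(lw[tail_ids])]] <- smoothed
  }
  list(lw = lw - max(lw), k = k)
}

#' Leave-one-out expected log predictive density
#'
#' Estimates the expected log pointwise predictive density (elpd) of a
#' fitted candidate by leave-one-observation-out cross-validation over the
#' training cells. The default estimator is Pareto-smoothed importance
#' sampling (PSIS) on the posterior draws; when the importance diagnostics
#' fail (tail shape k above `k_threshold`) or the panel has at most
#' `exact_cell_limit` cells, the affected observations are instead scored by
#' an exact refit with that observation left out.
#'
#' @param fit an `hc_fit`.
#' @param panel the training panel (defaults to the panel the fit stored).
#' @param method `"auto"` (PSIS with exact fallback), `"psis"`, or
#'   `"exact"` (refit for every observation).
#' @param k_threshold Pareto-k above which PSIS is distrusted (default 0.7).
#' @param exact_cell_limit panels with at most this many training cells use
#'   exact refits under `"auto"` (default 200).
#' @param refit_sampler optional [sampler_config()] for the refits (defaults
#'   to the fit's own sampler settings).
#' @return A `candidate_result` list: `label`, `elpd`, `se`, `pointwise`
#'   (per-cell elpd and Pareto-k), `method`, `n_refit`.
#' @export
loo_elpd <- function(fit, panel = NULL, method = c("auto", "psis", "exact"),
                     k_threshold = 0.7, exact_cell_limit = 200L,
                     refit_sampler = NULL) {
  stopifnot(inherits(fit, "hc_fit"))
  method <- match.arg(method)
  if (is.null(panel)) {
    panel <- fit$train
    class(panel) <- c("license_panel", "data.frame")
  }
  ll <- loglik_matrix(fit, panel)
  n <- ncol(ll)
  if (n == 0L) stop("loo_elpd: no training cells to score", call. = FALSE)

  if (method == "auto" && n <= exact_cell_limit) method <- "exact"

  khat <- rep(NA_real_, n)
  elpd_i <- numeric(n)
  refit_idx <- integer(0)

  if (method %in% c("auto", "psis")) {
    for (i in seq_len(n)) {
      sm <- psis_smooth(-ll[, i])
      khat[i] <- sm$k
      w <- sm$lw
      elpd_i[i] <- log_mean_exp(w + ll[, i]) - log_mean_exp(w)
    }
    if (method == "auto")
      refit_idx <- which(is.finite(khat) & khat > k_threshold)
  }
  if (method == "exact") refit_idx <- seq_len(n)

  if (length(refit_idx) > 0L) {
    cells <- attr(ll, "cells")
    sam <- if (is.null(refit_sampler)) fit$sampler else refit_sampler
    for (i in refit_idx) {
      drop_key <- paste(cells$province[i], cells$year[i])
      keep <- !(paste(panel$province, panel$year) %in% drop_key)
      sub <- panel[keep, , drop = FALSE]
      class(sub) <- c("license_panel", "data.frame")
      refit <- fit_trend_model(sub, fit$split, fit$spec,
                               do.call(prior_spec, fit$priors), sam)
      elpd_i[i] <- log_pointwise_density(
        refit, panel, cells = cells[i, c("province", "year"), drop = FALSE])
    }
  }

  structure(list(label = fit$spec$label,
                 elpd = sum(elpd_i),
                 se = sqrt(n * stats::var(elpd_i)),
                 pointwise = data.frame(cell = colnames(ll),
                                        elpd = elpd_i, pareto_k = khat,
                                        stringsAsFactors = FALSE),
                 method = method, n_refit = length(refit_idx), n = n),
            class = "candidate_result")
}

#' Fit and rank candidate model structures
#'
#' Fits every candidate on the training years, scores each by leave-one-out
#' elpd, and returns the highest-elpd spec together with the full comparison
#' table. Candidates whose sampler fails the split-Rhat convergence check are
#' excluded from the ranking and reported, never silently selected. Ties in
#' elpd are broken in favour of the structurally simpler candidate (fewer
#' model components).
#'
#' @param panel a [license_panel()].
#' @param split a [split_spec()].
#' @param candidates list of [model_spec()]s (default [default_candidates()]).
#' @param priors a [prior_spec()].
#' @param sampler a [sampler_config()].
#' @param loo_method passed to [loo_elpd()].
#' @return list with `best` (the winning `model_spec`), `table` (data.frame:
#'   candidate, elpd, se, rank, converged), and `fits` (named list of fits).
#' @export
select_model <- function(panel, split, candidates = default_candidates(),
                         priors = prior_spec(), sampler,
                         loo_method = "auto") {
  stopifnot(length(candidates) >= 1L)
  labels <- vapply(candidates, function(s) s$label, character(1))
  if (anyDuplicated(labels)) stop("select_model: duplicate candidate labels", call. = FALSE)

  fits <- list(); results <- list(); converged <- logical(length(candidates))
  for (j in seq_along(candidates)) {
    fit <- fit_trend_model(panel, split, candidates[[j]], priors, sampler)
    fits[[labels[j]]] <- fit
    converged[j] <- fit$diagnostics$usable
    results[[j]] <- if (converged[j])
      loo_elpd(fit, panel, method = loo_method)
    else list(elpd = NA_real_, se = NA_real_)
  }

  complexity <- vapply(candidates, function(s) {
    s$include_linear_trend + (s$rw_order == 1L) +
      switch(s$intercept_structure, "global" = 0L, "region-only" = 1L,
             "province-only" = 1L, "province-nested-in-region" = 2L)
  }, numeric(1))
  elpd <- vapply(results, function(r) r$elpd, numeric(1))
  ord <- order(-ifelse(is.na(elpd), -Inf, elpd), complexity, labels)
  rank <- integer(length(candidates)); rank[ord] <- seq_along(ord)
  rank[!converged] <- NA_integer_

  tab <- data.frame(candidate = labels, elpd = elpd,
                    se = vapply(results, function(r) r$se, numeric(1)),
                    rank = rank, converged = converged,
                    stringsAsFactors = FALSE)
  tab <- tab[order(ifelse(is.na(tab$rank), Inf, tab$rank)), ]
  rownames(tab) <- NULL

  ok <- which(converged)
  if (length(ok) == 0L) stop("select_model: no candidate converged", call. = FALSE)
  best_j <- ok[which.min(rank[ok])]
  list(best = candidates[[best_j]], table = tab, fits = fits)
}
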