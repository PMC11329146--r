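#' Tie-aware Spearman rank correlation
#'
#' Assigns midranks to tied values in each vector and returns the Pearson
#' product-moment correlation of the two rank vectors. This is the tie-aware
#' definition (the `6*sum(d^2)` shortcut is only exact without ties; the
#' excess-mortality covariate is reported in whole percent, so ties are
#' common).
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return rho in `[-1, 1]`.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y))
    stop("spearman_rho: x and y must have equal length", call. = FALSE)
  if (length(x) < 3L)
    stop("spearman_rho: need at least 3 pairs", call. = FALSE)
  if (anyNA(x) || anyNA(y))
    stop("spearman_rho: missing values not allowed", call. = FALSE)
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  if (stats::var(rx) == 0 || stats::var(ry) == 0)
    stop("spearman_rho: correlation undefined for a constant vector", call. = FALSE)
  stats::cor(rx, ry, method = "pearson")
}

#' Associate anomaly magnitudes with the excess-mortality covariate
#'
#' Pairs the absolute median-based deficit of each province with its
#' excess-mortality percentage and computes the tie-aware Spearman rank
#' correlation. The default policy pairs only provinces flagged as anomalous
#' decreases; `policy = "all"` pairs every province with a record. Lagged
#' pairings are supported by letting the covariate season differ from the
#' anomaly season (e.g. 2021 anomalies against 2020 mortality, probing a
#' harvesting-effect dynamic).
#'
#' @param records an `anomaly_records` data.frame for `anomaly_season`.
#' @param covariates data.frame `province`, `year`, `excess_mortality_pct`.
#' @param anomaly_season season-year of the anomalies.
#' @param covariate_season season-year of the covariate (default: same).
#' @param policy `"flagged"` (decreases only, default) or `"all"`.
#' @return An `association_result` list: `anomaly_season`,
#'   `covariate_season`, `n`, `rho`, `policy`, and the paired table `pairs`.
#' @export
associate_anomalies <- function(records, covariates, anomaly_season,
                                covariate_season = anomaly_season,
                                policy = c("flagged", "all")) {
  policy <- match.arg(policy)
  anomaly_season <- as.integer(anomaly_season)
  covariate_season <- as.integer(covariate_season)
  rec <- records[records$year == anomaly_season, , drop = FALSE]
  if (policy == "flagged") rec <- rec[rec$flag == "decrease", , drop = FALSE]
  cov <- covariates[covariates$year == covariate_season,
                    c("province", "excess_mortality_pct"), drop = FALSE]
  pairs <- merge(rec[, c("province", "region", "delta_median")], cov,
                 by = "province")
  if (nrow(pairs) < nrow(rec)) {
    miss <- setdiff(rec$province, pairs$province)
    stop("associate_anomalies: covariate missing for province(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (nrow(pairs) < 3L)
    stop("associate_anomalies: fewer than 3 paired provinces", call. = FALSE)
  pairs$abs_delta <- abs(pairs$delta_median)
  rho <- spearman_rho(pairs$excess_mortality_pct, pairs$abs_delta)
  structure(list(anomaly_season = anomaly_season,
                 covariate_season = covariate_season,
                 n = nrow(pairs), rho = rho, policy = policy,
                 pairs = pairs[order(-pairs$abs_delta, pairs$province), ]),
            class = "association_result")
}

#' @export
print.association_result <- function(x, ...) {
  cat("<association_result> anomalies ", x$anomaly_season,
      " vs excess mortality ", x$covariate_season,
      " (", x$policy, " provinces, n = ", x$n, ")\n",
      "  Spearman rho = ", round(x$rho, 3), "\n", sep = "")
  invisible(x)
}
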