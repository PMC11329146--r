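#' Flag and quantify counterfactual anomalies for one season
#'
#' Compares each province's observed license count for a post-period season
#' against its counterfactual predictive distribution. An observation is an
#' anomalous decrease when it falls strictly below the 2.5% predictive bound
#' and an anomalous increase when strictly above the 97.5% bound ("exceeds
#' the boundaries" is read as strictly outside; observations exactly on a
#' bound are not flagged). Every province gets a record — unflagged ones
#' carry `flag = "none"` — with the deficit quantified three ways:
#'
#' * `delta_median = pred_median - observed`: the most-likely deficit;
#' * `delta_lo = pred_lo - observed` and `delta_hi = pred_hi - observed`:
#'   the min-max deficit range against the 95% interval bounds;
#' * `pct_*`: the corresponding percentage changes of the observed count
#'   relative to each predicted value, `100 * (observed - pred) / pred`
#'   (negative for decreases, the convention used when reporting).
#'
#' Provinces present in the predictive summary but with no observed count
#' for the season are skipped and listed in attribute `skipped`.
#'
#' @param predictive_summary a `predictive_summary` from
#'   [predict_counterfactual()] (or any data.frame with columns `province`,
#'   `region`, `year`, `median`, `lo95`, `hi95`).
#' @param panel a [license_panel()] holding observed counts.
#' @param season_year the season (calendar year of its opening) to assess.
#' @return An `anomaly_records` data.frame, sorted by decreasing
#'   `delta_median`.
#' @export
flag_anomalies <- function(predictive_summary, panel, season_year) {
  season_year <- as.integer(season_year)
  ps <- predictive_summary[predictive_summary$year == season_year, , drop = FALSE]
  if (nrow(ps) == 0L)
    stop("flag_anomalies: predictive summary has no rows for season ",
         season_year, call. = FALSE)
  obs <- panel[panel$year == season_year, c("province", "count"), drop = FALSE]
  merged <- merge(ps, obs, by = "province", all.x = TRUE)
  skipped <- merged$province[is.na(merged$count)]
  merged <- merged[!is.na(merged$count), , drop = FALSE]

  rec <- data.frame(
    province = merged$province,
    region = merged$region,
    year = season_year,
    observed = merged$count,
    pred_median = merged$median,
    pred_lo = merged$lo95,
    pred_hi = merged$hi95,
    stringsAsFactors = FALSE
  )
  rec$flag <- ifelse(rec$observed < rec$pred_lo, "decrease",
                     ifelse(rec$observed > rec$pred_hi, "increase", "none"))
  rec$delta_median <- rec$pred_median - rec$observed
  rec$delta_lo <- rec$pred_lo - rec$observed
  rec$delta_hi <- rec$pred_hi - rec$observed
  rec$pct_median <- round(100 * (rec$observed - rec$pred_median) / rec$pred_median, 1)
  rec$pct_lo <- round(100 * (rec$observed - rec$pred_lo) / rec$pred_lo, 1)
  rec$pct_hi <- round(100 * (rec$observed - rec$pred_hi) / rec$pred_hi, 1)
  rec <- rec[order(-rec$delta_median, rec$province), ]
  rownames(rec) <- NULL
  class(rec) <- c("anomaly_records", "data.frame")
  attr(rec, "skipped") <- skipped
  rec
}

#' Aggregate anomalous decreases to regions
#'
#' Sums the median-based and min-max deficits over the provinces flagged as
#' anomalous decreases, per region and season. Provinces with `flag` other
#' than `"decrease"` never contribute. A requested region with no flagged
#' provinces yields a zero aggregate with `n_flagged = 0`.
#'
#' @param records an `anomaly_records` data.frame (one season).
#' @param region optional character vector restricting to specific regions;
#'   default aggregates every region present in `records`.
#' @return data.frame: `region`, `year`, `n_flagged`, `deficit_median`,
#'   `deficit_lo`, `deficit_hi`.
#' @export
aggregate_region <- function(records, region = NULL) {
  yrs <- unique(records$year)
  if (length(yrs) > 1L)
    stop("aggregate_region: records span multiple seasons; aggregate one at a time",
         call. = FALSE)
  regions <- if (is.null(region)) sort(unique(records$region)) else region
  flagged <- records[records$flag == "decrease", , drop = FALSE]
  out <- lapply(regions, function(r) {
    f <- flagged[flagged$region == r, , drop = FALSE]
    data.frame(region = r,
               year = if (length(yrs)) yrs else NA_integer_,
               n_flagged = nrow(f),
               deficit_median = sum(f$delta_median),
               deficit_lo = sum(f$delta_lo),
               deficit_hi = sum(f$delta_hi),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Bundled reference table of anomalous provinces
#'
#' Observed license counts, counterfactual predictions (median and 95%
#' bounds), reported deficits and provincial excess-mortality percentages
#' for the 29 Northern-Italy province-seasons flagged as anomalous decreases
#' in the 2020/2021 and 2021/2022 hunting seasons. Columns prefixed
#' `reported_` carry the deficits as published; the package recomputes them
#' from the observed/predicted columns.
#'
#' @return data.frame with one row per flagged province-season.
#' @export
reference_anomalies <- function() {
  path <- system.file("extdata", "northern_italy_anomalies.csv",
                      package = "huntcast", mustWork = TRUE)
  x <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = c(province = "character", region = "character"))
  x$year <- as.integer(x$year)
  x
}

#' Recompute anomaly records from the reference table
#'
#' Feeds the bundled observed/predicted values through [flag_anomalies()],
#' exactly as pipeline output would be; used for worked examples and for
#' checking the anomaly arithmetic against the published deficits.
#'
#' @param season_year 2020 or 2021.
#' @return An `anomaly_records` data.frame.
#' @export
reference_anomaly_records <- function(season_year) {
  ref <- reference_anomalies()
  ref <- ref[ref$year == season_year, , drop = FALSE]
  if (nrow(ref) == 0L) stop("no reference season ", season_year, call. = FALSE)
  ps <- data.frame(province = ref$province, region = ref$region,
                   year = ref$year, median = ref$pred_median,
                   lo95 = ref$pred_lo, hi95 = ref$pred_hi,
                   stringsAsFactors = FALSE)
  panel <- license_panel(data.frame(province = ref$province, region = ref$region,
                                    year = ref$year, count = ref$observed,
                                    stringsAsFactors = FALSE))
  flag_anomalies(ps, panel, season_year)
}
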