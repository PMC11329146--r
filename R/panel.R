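#' License count panels
#'
#' A license panel is a long-format table of annual license counts, one row
#' per province-year, with each province nested in exactly one region.
#' Internally it is a `data.frame` with columns `province`, `region`, `year`,
#' `count` and class `license_panel`. Missing province-years are represented
#' as absent rows, never as zero counts (a zero count is a real observation).
#'
#' @param x data.frame with columns `province`, `region`, `year`, `count`.
#' @return A validated `license_panel`.
#' @export
license_panel <- function(x) {
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  validate_panel(x)
  x <- data.frame(province = as.character(x$province),
                  region = as.character(x$region),
                  year = as.integer(x$year),
                  count = as.integer(round(x$count)),
                  stringsAsFactors = FALSE)
  x <- x[order(x$region, x$province, x$year), , drop = FALSE]
  rownames(x) <- NULL
  class(x) <- c("license_panel", "data.frame")
  x
}

validate_panel <- function(x) {
  required <- c("province", "region", "year", "count")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0L) {
    stop("panel schema error: missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(x) == 0L) return(invisible(TRUE))
  bad <- which(is.na(x$count) | x$count < 0 | abs(x$count - round(x$count)) > 1e-8)
  if (length(bad) > 0L) {
    stop("panel validation error: non-integer or negative count at row(s) ",
         paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
  }
  if (any(is.na(x$year)) || any(abs(as.numeric(x$year) - round(as.numeric(x$year))) > 1e-8)) {
    stop("panel validation error: years must be integers", call. = FALSE)
  }
  key <- paste(x$province, x$year, sep = "\r")
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1L]
    parts <- strsplit(d, "\r", fixed = TRUE)[[1L]]
    stop("panel validation error: duplicate (province, year) pair: (",
         parts[1L], ", ", parts[2L], ")", call. = FALSE)
  }
  reg_per_prov <- tapply(x$region, x$province, function(r) length(unique(r)))
  if (any(reg_per_prov > 1L)) {
    stop("panel validation error: province mapped to multiple regions: ",
         paste(names(reg_per_prov)[reg_per_prov > 1L], collapse = ", "),
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Read a license panel from a long-format CSV
#'
#' Canonical interchange format: UTF-8 CSV with header
#' `province,region,year,count`, one row per observed province-year.
#' Duplicate province-year rows, negative or non-integer counts, and a
#' province appearing under two regions are all rejected with a diagnostic
#' error.
#'
#' @param path CSV file path.
#' @return A `license_panel`.
#' @export
read_panel <- function(path) {
  if (!file.exists(path)) stop("panel file does not exist: ", path, call. = FALSE)
  x <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = c(province = "character", region = "character"))
  license_panel(x)
}

#' Write a license panel to CSV
#'
#' Writes the canonical long format with a stable column order and row sort
#' (region, province, year), so that writing the same panel twice is
#' byte-identical and `read_panel(write_panel(p)) == p`. Missing cells are
#' simply absent rows.
#'
#' @param panel A `license_panel`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  stopifnot(inherits(panel, "license_panel"))
  x <- as.data.frame(panel)[, c("province", "region", "year", "count")]
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Panel accessors
#'
#' @param panel A `license_panel`.
#' @return `panel_provinces`: character vector of province ids;
#'   `panel_years`: sorted integer years; `panel_region_of`: named character
#'   vector mapping province to region.
#' @export
panel_provinces <- function(panel) sort(unique(panel$province))

#' @rdname panel_provinces
#' @export
panel_years <- function(panel) sort(unique(panel$year))

#' @rdname panel_provinces
#' @export
panel_region_of <- function(panel) {
  u <- unique(panel[, c("province", "region")])
  stats::setNames(u$region, u$province)
}

#' Training/evaluation split of panel years
#'
#' @param training_years integer years used to fit the model.
#' @param evaluation_years integer years held out for counterfactual
#'   prediction; must all lie strictly after the last training year.
#' @return A `split_spec` list.
#' @export
split_spec <- function(training_years, evaluation_years) {
  training_years <- sort(as.integer(training_years))
  evaluation_years <- sort(as.integer(evaluation_years))
  if (length(intersect(training_years, evaluation_years)) > 0L)
    stop("split_spec: training and evaluation years must be disjoint", call. = FALSE)
  if (length(evaluation_years) > 0L && min(evaluation_years) <= max(training_years))
    stop("split_spec: evaluation years must be strictly after the last training year",
         call. = FALSE)
  structure(list(training_years = training_years,
                 evaluation_years = evaluation_years),
            class = "split_spec")
}

#' Excess mortality relative to a baseline period
#'
#' Computes the percentage increase of a target year's deaths over the mean
#' annual deaths of a baseline period (for the Italian provinces studied, the
#' baseline is 2015-2019):
#' `100 * (deaths[target] - mean(deaths[baseline])) / mean(deaths[baseline])`.
#' Negative values (fewer deaths than baseline) are allowed.
#'
#' @param deaths_by_year named numeric vector, names are years.
#' @param target_year year whose excess is computed.
#' @param baseline_years years defining the baseline mean.
#' @return Excess mortality in percent.
#' @export
compute_excess_mortality <- function(deaths_by_year, target_year, baseline_years) {
  if (length(baseline_years) == 0L)
    stop("compute_excess_mortality: baseline_years must be non-empty", call. = FALSE)
  yrs <- as.character(baseline_years)
  if (!all(yrs %in% names(deaths_by_year)))
    stop("compute_excess_mortality: baseline year(s) missing from deaths_by_year: ",
         paste(setdiff(yrs, names(deaths_by_year)), collapse = ", "), call. = FALSE)
  if (!as.character(target_year) %in% names(deaths_by_year))
    stop("compute_excess_mortality: target year missing from deaths_by_year", call. = FALSE)
  base <- mean(deaths_by_year[yrs])
  if (!is.finite(base) || base == 0)
    stop("compute_excess_mortality: baseline mean is zero or undefined", call. = FALSE)
  100 * (deaths_by_year[[as.character(target_year)]] - base) / base
}

#' Read or write a covariate table
#'
#' Covariate tables carry one row per (province, season-year) with the
#' province's excess-mortality percentage for that season. Format: CSV with
#' header `province,year,excess_mortality_pct`.
#'
#' @param path CSV file path.
#' @return A data.frame with columns `province`, `year`, `excess_mortality_pct`.
#' @export
read_covariates <- function(path) {
  if (!file.exists(path)) stop("covariate file does not exist: ", path, call. = FALSE)
  x <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = c(province = "character"))
  required <- c("province", "year", "excess_mortality_pct")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0L)
    stop("covariate schema error: missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (anyDuplicated(paste(x$province, x$year)))
    stop("covariate validation error: duplicate (province, year) row", call. = FALSE)
  x$year <- as.integer(x$year)
  x[order(x$province, x$year), required]
}

#' @rdname read_covariates
#' @param covariates covariate data.frame as returned by `read_covariates`.
#' @export
write_covariates <- function(covariates, path) {
  x <- covariates[order(covariates$province, covariates$year),
                  c("province", "year", "excess_mortality_pct")]
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
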