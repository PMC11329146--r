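#' End-to-end pipeline configuration
#'
#' Collects everything one run needs: the input panel (object or CSV path),
#' an optional covariate table, the training/evaluation split, the candidate
#' set (a single candidate skips model selection), priors, sampler settings
#' and the output directory. The resolved configuration is serialized into
#' the run manifest so any output can be reproduced.
#'
#' @param panel a [license_panel()] or path to a panel CSV.
#' @param covariates optional covariate data.frame or CSV path; when absent
#'   the association stage is skipped.
#' @param training_years,evaluation_years the split.
#' @param candidates list of [model_spec()]s; a single spec is fitted
#'   directly without selection.
#' @param priors a [prior_spec()].
#' @param chains,iter,warmup sampler settings.
#' @param seed master seed; per-stage seeds are derived from it.
#' @param outdir output directory (created if needed).
#' @return A `pipeline_config`.
#' @export
pipeline_config <- function(panel, covariates = NULL,
                            training_years = 2011:2019,
                            evaluation_years = 2020:2021,
                            candidates = list(model_spec()),
                            priors = prior_spec(),
                            chains = 2L, iter = 1000L, warmup = 1000L,
                            seed, outdir) {
  if (missing(seed)) stop("pipeline_config: seed is mandatory", call. = FALSE)
  if (missing(outdir)) stop("pipeline_config: outdir is mandatory", call. = FALSE)
  split <- split_spec(training_years, evaluation_years)
  structure(list(panel = panel, covariates = covariates, split = split,
                 candidates = candidates, priors = priors,
                 chains = as.integer(chains), iter = as.integer(iter),
                 warmup = as.integer(warmup),
                 seed = as.integer(seed), outdir = outdir),
            class = "pipeline_config")
}

#' Run the full counterfactual anomaly pipeline
#'
#' Stages, in order: (optional) model selection by leave-one-out elpd; fit
#' of the chosen structure on the training years; posterior-predictive
#' counterfactuals for the evaluation years; anomaly flagging and regional
#' aggregation per season; Spearman association with the covariate per
#' season, plus the one-season-lagged pairing when two or more evaluation
#' seasons are present. All outputs are CSV (dot decimal separator, no
#' thousands grouping) plus a JSON manifest; reruns with the same
#' configuration and seed are byte-identical.
#'
#' @param config a [pipeline_config()].
#' @param quiet suppress stage messages?
#' @return Invisibly, a list with the fitted model, predictive summary,
#'   anomaly records, regional aggregates, association results, selection
#'   table (or NULL) and manifest.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (!quiet) message("[huntcast] ", ...)
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)

  panel <- if (is.character(config$panel)) read_panel(config$panel)
           else license_panel(config$panel)
  covariates <- if (is.null(config$covariates)) NULL
                else if (is.character(config$covariates)) read_covariates(config$covariates)
                else config$covariates
  split <- config$split
  sam <- sampler_config(chains = config$chains, iter = config$iter,
                        warmup = config$warmup, seed = config$seed)

  selection_table <- NULL
  if (length(config$candidates) > 1L) {
    say("stage select: ", length(config$candidates), " candidates")
    sel <- select_model(panel, split, config$candidates, config$priors, sam)
    best <- sel$best
    selection_table <- sel$table
    utils::write.csv(selection_table,
                     file.path(config$outdir, "model_comparison.csv"),
                     row.names = FALSE, quote = FALSE)
  } else {
    best <- config$candidates[[1L]]
  }

  say("stage fit: ", best$label)
  fit <- fit_trend_model(panel, split, best, config$priors, sam)
  if (!fit$diagnostics$usable)
    warning("run_pipeline: selected model failed convergence check (max Rhat = ",
            round(fit$diagnostics$max_rhat, 3), ")", call. = FALSE)

  say("stage predict: years ", paste(split$evaluation_years, collapse = ", "))
  pred <- predict_counterfactual(fit, split$evaluation_years,
                                 seed = config$seed + 1L)
  utils::write.csv(format_num(pred),
                   file.path(config$outdir, "predictive_summary.csv"),
                   row.names = FALSE, quote = FALSE)

  say("stage detect")
  records <- list(); aggregates <- list()
  for (yr in split$evaluation_years) {
    rec <- flag_anomalies(pred, panel, yr)
    records[[as.character(yr)]] <- rec
    aggregates[[as.character(yr)]] <- aggregate_region(rec)
  }
  all_rec <- do.call(rbind, records)
  utils::write.csv(format_num(all_rec),
                   file.path(config$outdir, "anomalies.csv"),
                   row.names = FALSE, quote = FALSE)
  all_agg <- do.call(rbind, aggregates)
  utils::write.csv(format_num(all_agg),
                   file.path(config$outdir, "regional_aggregates.csv"),
                   row.names = FALSE, quote = FALSE)

  associations <- NULL
  if (!is.null(covariates)) {
    say("stage associate")
    rows <- list()
    for (yr in split$evaluation_years) {
      rows[[length(rows) + 1L]] <- try_association(records[[as.character(yr)]],
                                                   covariates, yr, yr)
    }
    if (length(split$evaluation_years) >= 2L) {
      yrs <- split$evaluation_years
      rows[[length(rows) + 1L]] <- try_association(
        records[[as.character(yrs[2L])]], covariates, yrs[2L], yrs[1L])
    }
    associations <- do.call(rbind, rows)
    utils::write.csv(format_num(associations),
                     file.path(config$outdir, "associations.csv"),
                     row.names = FALSE, quote = FALSE)
  } else {
    say("stage associate: skipped (no covariates)")
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("huntcast")),
    seed = config$seed,
    model = best$label,
    training_years = split$training_years,
    evaluation_years = split$evaluation_years,
    sampler = list(chains = config$chains, iter = config$iter,
                   warmup = config$warmup),
    priors = fit$priors,
    diagnostics = list(max_rhat = fit$diagnostics$max_rhat,
                       min_ess = min(fit$diagnostics$ess),
                       usable = fit$diagnostics$usable),
    n_provinces = length(fit$provinces),
    n_regions = length(fit$regions),
    association_skipped = is.null(covariates),
    outputs = list.files(config$outdir, pattern = "\\.csv$")
  )
  jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  say("done")
  invisible(list(fit = fit, predictive_summary = pred,
                 anomalies = all_rec, regional_aggregates = all_agg,
                 associations = associations,
                 selection_table = selection_table, manifest = manifest))
}

try_association <- function(rec, covariates, anomaly_season, covariate_season) {
  res <- tryCatch(
    associate_anomalies(rec, covariates, anomaly_season, covariate_season),
    error = function(e) NULL)
  if (is.null(res)) {
    data.frame(anomaly_season = anomaly_season,
               covariate_season = covariate_season,
               n = NA_integer_, rho = NA_real_, policy = "flagged",
               stringsAsFactors = FALSE)
  } else {
    data.frame(anomaly_season = res$anomaly_season,
               covariate_season = res$covariate_season,
               n = res$n, rho = res$rho, policy = res$policy,
               stringsAsFactors = FALSE)
  }
}

# locale-proof numeric formatting for CSV export (dot separator, no grouping)
format_num <- function(df) {
  df <- as.data.frame(df)
  num <- vapply(df, is.numeric, logical(1)) & !vapply(df, is.integer, logical(1))
  for (j in which(num)) df[[j]] <- formatC(df[[j]], format = "fg", digits = 10)
  df
}
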